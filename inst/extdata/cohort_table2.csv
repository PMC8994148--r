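term,us_total_pm,us_gbs_pm,us_nongbs_pm,us_p,eu_total_pm,eu_gbs_pm,eu_nongbs_pm,eu_p,us_vs_eu_p
Pyrexia,138.85,58.23,139.88,<.001,140.86,79.44,141.93,.01,.55
Injection-site erythema,126.36,2.01,127.94,<.001,15.53,0,15.80,.06,<.001
Pain,125.40,113.45,125.55,.25,29.77,112.15,28.34,<.001,<.001
Injection-site pain,119.16,7.03,120.58,<.001,30.97,4.67,31.43,.03,<.001
Erythema,89.69,3.01,90.79,<.001,23.37,4.67,23.70,.07,<.001
Pain in extremity,86.79,73.29,86.97,.13,46.74,177.57,44.46,<.001,<.001
Injection-site swelling,86.07,3.01,87.13,<.001,12.48,0,12.70,.10,<.001
Headache,77.52,61.24,77.73,.05,103.16,88.79,103.41,.49,<.001
Pruritus,71.33,2.01,72.22,<.001,23.53,18.69,23.61,.64,<.001
Chills,68.46,22.09,69.06,<.001,37.21,32.71,37.29,.73,<.001
Dizziness,63.45,32.13,63.85,<.001,60.02,65.42,59.93,.74,.14
Nausea,62.70,25.10,63.18,<.001,55.14,23.36,55.70,.04,.001
Urticaria,60.75,2.01,61.49,<.001,27.85,0,28.34,.01,<.001
Rash,59.50,10.04,60.13,<.001,26.57,9.35,26.87,.11,<.001
Injection-site warmth,55.91,<0.01,56.62,<.001,4.08,0,4.15,.34,<.001
Dyspnea,50.67,57.23,50.58,.34,47.94,70.09,47.55,.13,.19
Myalgia,49.52,49.20,49.52,.96,66.43,56.07,66.61,.54,<.001
Vomiting,45.60,26.10,45.85,.003,42.26,37.38,42.34,.72,.09
Asthenia,44.78,296.18,41.58,<.001,39.62,121.50,38.19,<.001,.01
Fatigue,37.96,59.24,37.69,<.001,72.91,135.51,71.82,<.001,<.001
Paresthesia,37.57,332.33,33.81,<.001,43.06,345.79,37.78,<.001,.003
Cough,37.16,32.13,37.23,.40,38.02,23.36,38.27,.26,.64
"Edema, peripheral",35.20,9.04,35.54,<.001,5.52,4.67,5.54,.87,<.001
Malaise,32.22,27.11,32.29,.36,55.62,56.07,55.61,.98,<.001
"Skin, warm",31.34,1.00,31.73,<.001,1.92,0,1.95,.52,<.001
Hypesthesia,31.31,289.16,28.03,<.001,26.65,285.05,22.15,<.001,.005
Swelling,30.76,3.01,31.11,<.001,5.28,0,5.37,.28,<.001
Arthralgia,28.59,19.08,28.71,.07,39.06,37.38,39.08,.90,<.001
Injection-site edema,28.09,1.00,28.44,<.001,2.40,0,2.44,.47,<.001
Injection-site hypersensitivity,26.38,2.01,26.69,<.001,0.24,0,0.24,.82,<.001
Diarrhea,24.30,24.10,24.31,.97,27.29,42.06,27.03,.18,.05
Hyperhidrosis,23.08,7.03,23.28,<.001,18.65,9.35,18.81,.31,.002
Tremor,21.82,14.06,21.91,.09,9.68,32.71,9.28,<.001,<.001
Injection-site pruritus,21.26,<0.01,21.53,<.001,3.60,0,3.66,.38,<.001
Injected-limb mobility decreased,20.78,2.01,21.02,<.001,2.96,0,3.01,.42,<.001
Feeling hot,19.88,<0.01,20.14,<.001,10.40,9.35,10.42,.88,<.001
Injection-site reaction,19.39,1.00,19.62,<.001,8.48,0,8.63,.17,<.001
Musculoskeletal pain,18.91,12.05,19.00,.11,11.20,46.73,10.59,<.001,<.001
Injection-site induration,18.86,<0.01,19.10,<.001,4.16,0,4.23,.34,<.001
Cellulitis,18.63,1.00,18.86,<.001,2.16,0,2.20,.49,<.001
Muscular weakness,17.75,230.92,15.03,<.001,25.13,266.36,20.93,<.001,<.001
Vasodilatation,17.61,2.01,17.81,<.001,0.32,0,0.33,.79,<.001
Neck pain,17.51,16.06,17.53,.73,7.20,4.67,7.25,.66,<.001
Mobility decreased,16.32,24.10,16.22,.05,3.92,14.02,3.75,.02,<.001
Immediate postinjection reaction,16.28,3.01,16.45,<.001,0,0,0,na,na
Chest pain,16.21,18.07,16.18,.64,13.93,14.02,13.92,.99,.06
"Rash, erythematous",15.61,2.01,15.79,<.001,4.88,0,4.97,.30,<.001
Injection-site rash,15.45,1.00,15.63,<.001,1.36,0,1.38,.59,<.001
Syncope,15.42,8.03,15.52,.06,29.21,4.67,29.64,.03,<.001
Tenderness,15.40,3.01,15.56,.001,1.20,4.67,1.14,.14,<.001
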