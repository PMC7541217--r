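name,le_mean,le_sd,sdr2,sdr2.5,sdr3,sdr4
Sella,0.86,1.92,96.67,97.33,98.00,98.00
Nasion,1.28,1.03,81.33,86.00,90.00,96.67
Orbitale,2.11,2.77,77.33,87.33,94.00,96.67
Porion,1.89,1.67,58.00,66.00,72.67,86.67
A-point,2.07,2.53,52.00,62.00,74.00,87.33
B-point,2.08,1.77,79.33,88.67,93.33,96.67
Pogonion,1.17,0.81,82.67,90.67,96.00,100.00
Menton,1.11,2.82,95.33,97.33,98.00,98.67
Gnathion,0.97,0.56,92.00,97.33,98.67,98.67
Gonion,2.39,4.77,63.33,75.33,85.33,92.67
Lower incisal incision,1.35,2.19,84.00,90.67,93.33,96.67
Upper incisal incision,0.90,0.75,93.33,97.33,98.00,99.33
Upper lip,1.32,0.83,96.67,100.00,100.00,100.00
Lower lip,1.28,0.85,97.33,98.67,98.67,99.33
Subnasale,1.22,1.56,84.00,92.00,95.33,96.67
Soft tissue pogonion,2.62,2.07,82.67,92.67,95.33,97.33
Posterior Nasal Spine,1.23,0.91,90.00,94.00,95.33,98.00
Anterior Nasal Spine,1.52,1.56,78.67,87.33,90.67,93.33
Articulare,1.70,1.77,75.33,83.33,86.67,90.67
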