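parameter,row,true_label,class_labels,p1,p2,p3,p4
ANB,1,1,1;2;3,65.75,10.96,23.29,NA
ANB,2,2,1;2;3,23.64,70.91,5.45,NA
ANB,3,3,1;2;3,4.96,0.83,94.21,NA
SNB,1,1,1;2;3,73.24,4.23,22.54,NA
SNB,2,2,1;2;3,38.46,58.97,2.56,NA
SNB,3,3,1;2;3,5.04,0.00,94.96,NA
SNA,1,1,1;2;3,67.62,16.19,16.19,NA
SNA,2,2,1;2;3,18.89,80.00,1.11,NA
SNA,3,3,1;2;3,25.93,3.70,70.37,NA
MW,1,1,1;3;4;5,75.00,1.19,17.86,5.95
MW,2,3,1;3;4;5,0.00,89.76,2.04,8.16
MW,3,4,1;3;4;5,13.89,0.00,86.11,0.00
MW,4,5,1;3;4;5,15.91,13.64,0.00,70.45
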