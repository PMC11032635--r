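study_id,task,rt_congruent_ms,rt_neutral_ms,rt_incongruent_ms,r_printed
fl01,flanker,638,646,714,0.118
fl02,flanker,493.5,486.8,511.3,-0.273
fl03,flanker,419.5,411.5,512.2,-0.079
fl04,flanker,313.5,350.5,405,0.679
fl05,flanker,484,495.8,504.6,1.341
fl06,flanker,477.7,496.5,514.3,1.056
fl07,flanker,463.6,489.5,525.3,0.723
fl08,flanker,495,494.5,499.5,-0.100
fl09,flanker,477.8,469.7,485.7,-0.506
fl10,flanker,343,350.5,362.5,0.625
fl11,flanker,443.9,457.4,484.7,0.495
fl12,flanker,788,805.5,831.5,0.673
fl13,flanker,351.8,378.3,414.8,0.730
fl14,flanker,572,587,618,0.484
fl15,flanker,411,412,448,0.028
fl16,flanker,595.5,599.5,611.8,0.325
si01,simon,346,351.5,370,0.297
si02,simon,504.1,518.9,544.6,0.576
si03,simon,408.7,434.3,461.3,0.948
si04,simon,393.5,347,421,-0.628
si05,simon,1019,1014.5,1033.5,-0.237
si06,simon,637.2,631.8,700.8,-0.078
si07,simon,307.5,351.6,427,0.585
si08,simon,419.9,421.8,450.1,0.067
si09,simon,644.6,669,681.4,1.968
si10,simon,402.7,409.2,409.5,21.667
si11,simon,397.9,423.7,442.9,1.351
si12,simon,406,412.5,421,0.765
si13,simon,347,355.5,365,0.895
si14,simon,592,639,684,1.044
si15,simon,445.3,462.3,486,0.718
si16,simon,355.6,356.8,363.3,0.179
si17,simon,533,570.5,579,4.412
st01,stroop,672,701,789,0.330
st02,stroop,797.9,739,879.5,-0.419
st03,stroop,699.5,700,944,0.002
st04,stroop,536.6,590.8,719.1,0.422
st05,stroop,516,529,560,0.419
st06,stroop,659.3,670.5,737.3,0.168
st07,stroop,522.3,526.3,648.3,0.033
st08,stroop,639.5,642,754.5,0.022
st09,stroop,662.5,682,739.5,0.339
st10,stroop,632.2,682.3,852,0.295
st11,stroop,715,742,772,0.900
st12,stroop,632.1,660.2,726.7,0.423
st13,stroop,608.7,638.5,700,0.485
st14,stroop,681.3,679.5,703.8,-0.072
st15,stroop,619.5,637.5,670.9,0.540
st16,stroop,677.5,696.5,828.5,0.144
st17,stroop,963.3,1145.5,1459,0.581
st18,stroop,705,725,771,0.435
st19,stroop,562.7,614,693.3,0.647
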