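mutant,qv_model,qv_v0,se_qv_v0,qv_z0,se_qv_z0,qv_v1,se_qv_v1,qv_z1,se_qv_z1,qv2_vhalf,se_qv2_vhalf,qv2_z,se_qv2_z,gv_vhalf,se_gv_vhalf,gv_z,se_gv_z,inac_vhalf,se_inac_vhalf,inac_z,se_inac_z
WT,,,,,,,,,,,,,,-26.0,0.6,2.9,0.2,-36,0,4.6,0.3
W434F,three_state,-51.9,1.9,1.7,0.2,-46.5,1.1,3.4,0.1,,,,,,,,,,,,
L361R,two_state,,,,,,,,,-124.3,1.1,1.5,0.1,-89.7,0.4,2.2,0.1,,,,
L361R:W434F,two_state,,,,,,,,,-81.5,0.3,1.0,0.0,,,,,,,,
L361R:L409A,,,,,,,,,,,,,,-69.4,1.1,1.8,0.1,,,,
L361R:L409A:W434F,two_state,,,,,,,,,-76.2,1.1,1.1,0.0,,,,,,,,
L361R:S411A,,,,,,,,,,,,,,-79.2,1.2,1.7,0.1,,,,
L361R:S411A:W434F,two_state,,,,,,,,,-97.4,0.5,1.2,0.0,,,,,,,,
L361R:S412A,,,,,,,,,,,,,,-76.4,1.0,1.8,0.1,,,,
L361R:S412A:W434F,two_state,,,,,,,,,-93.2,0.5,1.1,0.1,,,,,,,,
L361R:F433A,,,,,,,,,,,,,,-50.1,1.0,1.6,0.1,,,,
L361R:F433A:W434F,two_state,,,,,,,,,-89.3,1.7,0.9,0.1,,,,,,,,
L366H,,,,,,,,,,,,,,-52.5,1.2,1.6,0.1,,,,
L366H:W434F,two_state,,,,,,,,,-87.2,1.2,1.1,0.1,-52,1,2.0,0.1,,,,
L366H:V478W,two_state,,,,,,,,,-89.8,0.5,1.1,0.1,,,,,,,,
L409A,,,,,,,,,,,,,,0.2,0.6,1.8,0.1,-20.6,0.5,3.5,0.2
L409A:W434F,three_state,-62.4,0.6,2.2,0.1,-36.3,0.2,4.2,0.1,,,,,,,,,,,,
S411A,,,,,,,,,,,,,,-11.9,1.0,1.9,0.1,-28.7,0.4,4.4,0.3
S411A:W434F,three_state,-67.2,0.6,1.7,0.1,-44.4,0.4,3.1,0.1,,,,,,,,,,,,
S412A,,,,,,,,,,,,,,-20.0,0.6,2.5,0.1,-28.0,0.6,3.9,0.3
S412A:W434F,three_state,-60.9,0.6,1.7,0.1,-37.2,0.3,3.5,0.1,,,,,,,,,,,,
F433A,,,,,,,,,,,,,,6.6,0.7,1.7,0.1,-14.6,0.8,2.6,0.2
F433A:W434F,two_state,,,,,,,,,-44.0,0.3,1.8,0.1,,,,,,,,
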