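label,v_median_mV,se_mV,role
V478W,-44.29,1.24,parent
S411A:V478W,-48.54,1.13,single1
F433A:V478W,-54.34,1.38,single2
S411A:F433A:V478W,-52.21,1.11,double
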