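"peptide","intensity"
"ELAAVPSR",2e+06
"TYMVR",1500000
"IYAVSR",1e+06
"AGDSSLK",9e+05
"VVDDAWK",8e+05
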