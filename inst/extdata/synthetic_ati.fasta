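>SYN_ATI_A synthetic alpha-amylase/trypsin inhibitor-like chain A (stand-in)
SAGTKELAAVPSRIYAVSRTCGLGGPYGPVDPSPVLKACGVSIGPVVPLPVLKQQCCRGD
LAAIPAGCRLDSMPGHCGVSTSKVVDDAWKGPLSGGERAELTADNHQWCKAPGAAGGK
>SYN_ATI_B synthetic alpha-amylase/trypsin inhibitor-like chain B (stand-in)
GVFDKTYMVRLVPYCRANWCEPGLVIPLNPLPSCRQLAEVPHDCRSGNVGESGLIDLPGC
PREMQWDFVRAGDSSLKWDETNPGHGCQMKGVTSAEFKTLHGRPFCYALGAEGTTT
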