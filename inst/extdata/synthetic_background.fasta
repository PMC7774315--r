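>SYN_BG_1 synthetic background protein (stand-in)
MGSSHHLVPRGSAGTENLYFQGAMDPEFKGLVNAK
>SYN_BG_2 synthetic background protein (stand-in)
TTAEDLGAKWDSETNPAHAEQFKGVLDNPR
>SYN_BG_3 synthetic background protein (stand-in)
AVDLSPKGPLSGGERTLNNPQAFAWK
>SYN_BG_4 synthetic background protein (stand-in)
MKVAVLGAAGGIGQALALLLKTQLPSGSER
>SYN_BG_5 synthetic background protein (stand-in)
PNNLQLDETGAHWAVSRDDLMTYMAK
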