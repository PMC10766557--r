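primaryid$caseid$outc_cod
1001$C100$HO
1003$C102$DE
9999$C999$OT
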