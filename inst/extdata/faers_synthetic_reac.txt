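primaryid$caseid$pt
1001$C100$Headache
1001$C100$Nausea
1002$C101$Pyrexia
1003$C102$Headache
9999$C999$Orphan event
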