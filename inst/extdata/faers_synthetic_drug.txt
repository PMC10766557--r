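primaryid$caseid$drug_seq$drugname
1001$C100$1$ASPIRIN
1001$C100$2$LISINOPRIL
1002$C101$1$AMOXICILLIN
1003$C102$1$ASPIRIN
9999$C999$1$ORPHANDRUG
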