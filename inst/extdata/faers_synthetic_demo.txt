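primaryid$caseid$caseversion$fda_dt$age$age_cod$sex$wt$wt_cod$occp_cod$occr_country
1001$C100$1$20200415$62$YR$F$70$KG$MD$US
1002$C101$1$20200501$24$MON$M$12$KG$CN$US
1003$C102$2$20190620$7$DEC$F$$$PH$FR
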