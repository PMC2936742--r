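rule_id,trigger_left,trigger_right,removed_left,removed_right
atp_adp,ATP,ADP,,
atp_amp,ATP,AMP,,
adp_amp,ADP,AMP,,
gtp_gdp,GTP,GDP,,
gtp_gmp,GTP,GMP,,
utp_udp,UTP,UDP,,
ctp_cdp,CTP,CDP,,
datp_dadp,DATP,DADP,,
dgtp_dgdp,DGTP,DGDP,,
ttp_tdp,TTP,TDP,,
nad_nadh,NAD,NADH,,
nadp_nadph,NADP,NADPH,,
fad_fadh2,FAD,FADH2,,
fmn_fmnh2,FMN,FMNH2,,
sam_sah,S-ADENOSYLMETHIONINE,ADENOSYL-HOMO-CYS,,
glt_akg,GLT,2-KETOGLUTARATE,,
gln_glt,GLN,GLT,,
thf_methylene_thf,THF,METHYLENE-THF,,
thf_formyl_thf,THF,10-FORMYL-THF,,
ubiquinone,UBIQUINONE-8,UBIQUINOL-8,,
menaquinone,MENAQUINONE,REDUCED-MENAQUINONE,,
glutathione,OXIDIZED-GLUTATHIONE,GLUTATHIONE,,
thioredoxin,OX-THIOREDOXIN,RED-THIOREDOXIN,,
paps_pap,PAPS,3-5-ADP,,
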