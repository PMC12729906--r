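# Defined daily dose (DDD) reference for the 18 stewardship-targeted agents.
# WHO-style ATC/DDD convention (assumed average adult maintenance dose per day
# for the main indication), grams per DDD. Route-specific rows override the
# route-independent default row (empty route). The WHO index is versioned;
# substitute your site's adopted version for production analyses.
# colistin is expressed as grams of colistimethate base (9 MU ~ 0.72 g);
# amphotericin and daptomycin assume a 70 kg adult at the usual mg/kg dose.
drug,route,ddd_grams
cefepime,,4
linezolid,,1.2
teicoplanin,,0.4
tigecycline,,0.1
ertapenem,,1
amikacin,,1
colistin,,0.72
ciprofloxacin,oral,1
ciprofloxacin,injectable,0.5
moxifloxacin,,0.4
aztreonam,,4
ceftazidime,,4
daptomycin,,0.28
anidulafungin,,0.1
fluconazole,,0.2
amphotericin,,0.035
caspofungin,,0.05
posaconazole,,0.3
voriconazole,,0.4
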