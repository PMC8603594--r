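drug,prevalence_pct,n_beneficiaries
amiodarone,27.3,706029
methotrexate,23.1,527799
bupropion,18.7,1714050
tramadol,16.3,4266058
trazodone,14.6,2915625
cyclobenzaprine,14.3,1860548
fluoxetine,11.5,1334205
ondansetron,10.5,3153351
quetiapine,10.3,1247664
citalopram,9.8,1684688
mirtazapine,8.3,1345516
escitalopram,7.7,2007721
sertraline,7.1,2683062
venlafaxine,6.7,1075483
oxycodone,5.9,4050823
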