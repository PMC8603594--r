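drug,class
bupropion,psychotropic
trazodone,psychotropic
escitalopram,psychotropic
sertraline,psychotropic
fluoxetine,psychotropic
mirtazapine,psychotropic
citalopram,psychotropic
venlafaxine,psychotropic
quetiapine,psychotropic
amiodarone,cardiovascular
diltiazem,cardiovascular
digoxin,cardiovascular
tramadol,opiate
oxycodone,opiate
aspirin,hemostasis
warfarin,hemostasis
clopidogrel,hemostasis
apixaban,hemostasis
methotrexate,immunosuppressant
ibuprofen,nsaid
cyclobenzaprine,muscle_relaxant
ondansetron,antiemetic
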