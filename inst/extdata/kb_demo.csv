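drug_a,drug_b,severity,ades,mechanisms
amiodarone,warfarin,monitor_closely,bleeding,"[{""kind"":""pk_inhibition"",""inhibitor"":""amiodarone"",""substrate"":""warfarin"",""enzyme"":""CYP2C9""}]"
aspirin,warfarin,generally_avoid,bleeding,"[{""kind"":""shared_ade"",""ade_term"":""bleeding""}]"
bupropion,mirtazapine,monitor_closely,seizures;serotonin_syndrome,"[{""kind"":""pk_inhibition"",""inhibitor"":""bupropion"",""substrate"":""mirtazapine"",""enzyme"":""CYP2D6""},{""kind"":""shared_ade"",""ade_term"":""serotonin_syndrome""}]"
fluoxetine,mirtazapine,monitor_closely,serotonin_syndrome,"[{""kind"":""pk_inhibition"",""inhibitor"":""fluoxetine"",""substrate"":""mirtazapine"",""enzyme"":""CYP2D6""},{""kind"":""shared_ade"",""ade_term"":""serotonin_syndrome""}]"
bupropion,fluoxetine,generally_avoid,seizures;serotonin_syndrome,"[{""kind"":""pk_inhibition"",""inhibitor"":""bupropion"",""substrate"":""fluoxetine"",""enzyme"":""CYP2D6""},{""kind"":""shared_ade"",""ade_term"":""serotonin_syndrome""}]"
fluoxetine,tramadol,monitor_closely,serotonin_syndrome;seizures,"[{""kind"":""shared_ade"",""ade_term"":""serotonin_syndrome""}]"
tramadol,trazodone,monitor_closely,serotonin_syndrome;seizures,"[{""kind"":""shared_ade"",""ade_term"":""serotonin_syndrome""}]"
amiodarone,digoxin,generally_avoid,bradycardia;av_block,"[{""kind"":""pk_inhibition"",""inhibitor"":""amiodarone"",""substrate"":""digoxin""}]"
ondansetron,quetiapine,monitor_closely,prolonged_qt,"[{""kind"":""shared_ade"",""ade_term"":""prolonged_qt""}]"
amiodarone,quetiapine,monitor_closely,prolonged_qt,"[{""kind"":""shared_ade"",""ade_term"":""prolonged_qt""}]"
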