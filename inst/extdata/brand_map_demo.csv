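brand,generic
coumadin,warfarin
prozac,fluoxetine
wellbutrin,bupropion
cordarone,amiodarone
remeron,mirtazapine
ultram,tramadol
zofran,ondansetron
seroquel,quetiapine
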