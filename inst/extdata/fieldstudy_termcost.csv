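term,cost,n_planned,n_realized
short,low,222,118
short,medium,44,19
short,high,0,0
medium,low,88,45
medium,medium,94,11
medium,high,33,7
long,low,0,0
long,medium,44,9
long,high,111,1
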