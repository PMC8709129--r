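"parameter","level","value_mm"
"aml","p05",13.63
"aml","p50",20.6
"aml","p95",27.57
"p1","p05",6.85
"p1","p50",11
"p1","p95",15.15
"p2","p05",8.25
"p2","p50",12.9
"p2","p95",17.55
"p3","p05",6.08
"p3","p50",10.4
"p3","p95",14.72
"d_am","L1",21.5
"d_am","L2",22
"d_am","L3",22.5
"d_am","L4",23
"d_am","L5",23.5
"d_ic","L1",17.65
"d_ic","L2",18.15
"d_ic","L3",18.65
"d_ic","L4",19.15
"d_ic","L5",19.65
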