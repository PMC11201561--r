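block,outcome,initial,low,medium,high
lungrads,event,low,2,5,5
lungrads,event,medium,0,11,4
lungrads,event,high,1,5,20
lungrads,nonevent,low,89,46,9
lungrads,nonevent,medium,67,67,2
lungrads,nonevent,high,8,76,33
brock,event,low,1,4,0
brock,event,medium,2,14,11
brock,event,high,0,3,18
brock,nonevent,low,105,57,0
brock,nonevent,medium,54,110,19
brock,nonevent,high,5,22,25
lcrp_baseline,event,low,3,2,0
lcrp_baseline,event,medium,0,19,10
lcrp_baseline,event,high,0,0,19
lcrp_baseline,nonevent,low,136,22,0
lcrp_baseline,nonevent,medium,28,165,20
lcrp_baseline,nonevent,high,0,2,24
lcrp_followup,event,low,2,1,0
lcrp_followup,event,medium,1,14,8
lcrp_followup,event,high,0,6,21
lcrp_followup,nonevent,low,123,32,0
lcrp_followup,nonevent,medium,41,149,18
lcrp_followup,nonevent,high,0,8,26
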