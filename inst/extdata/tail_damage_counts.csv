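tail,straw,stock,pens_batch134,pens_batch2,pens_total,no_damage_pens,damage_pairs
docked,with,low,12,3,15,14,1
docked,with,high,12,3,15,11,3
docked,without,low,12,3,15,10,3
docked,without,high,12,3,15,8,7
undocked,with,low,12,1,13,5,1
undocked,with,high,12,1,13,3,4
undocked,without,low,12,1,13,4,4
undocked,without,high,12,1,13,1,0
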