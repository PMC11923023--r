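block_id,treatment,alive_females,dead_females,total_eggs,damage_area,assay_days
B1,inducer_25C,14,0,140,14,2
B1,suppressor_32C,10,4,60,30,2
B2,inducer_25C,12,2,96,,2
B2,suppressor_32C,0,14,0,7,2
B3,inducer_25C,13,1,130,26,2
B3,suppressor_32C,9,5,45,18,2
B4,inducer_25C,14,0,70,21,2
B4,suppressor_32C,11,3,88,,2
B5,inducer_25C,8,6,44,22,2
B5,suppressor_32C,7,7,21,10.5,2
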