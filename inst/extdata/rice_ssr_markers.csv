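marker,chromosome,position_cM,motif,annealing_temp_C,repeat_category,expected_size_bp
RM1,1,94.9,(GA)14,55,di,84
RM19,3,94.9,(GA)17,55,di,213
RM18,6,58.4,(CT)8,60,di,224
RM124,2,216.4,(GA)21,60,di,106
RM144,5,0,(AG)20,60,di,116
RM162,10,150.1,(GATG)5,55,tetra,328
RM271,9,26.7,(CT)16,55,di,126
RM316,12,108.3,(GA)11,55,di,108
RM388,4,0,(AT)14(GT)21,55,complex,104
RM433,8,0,(CT)13,55,di,109
RM452,5,26.7,(AG)11,50,di,65
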