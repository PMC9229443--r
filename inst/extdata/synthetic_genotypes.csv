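line_id,M1,M2,M3,M4,M5,M6,M7,M8,M9,M10,M11
P1,100,126,140,162,184,204,220,246,260,282,306
P2,100,126,142,166,186,204,226,242,262,284,302
P3,104,124,144,164,182,202,224,244,264,282,304
P4,100,126,146,160,180,200,224,246,260,286,306
P5,106,120,140,164,182,204,224,246,266,282,300
P6,106,124,142,160,182,200,220,240,262,284,306
P7,106,124,140,166,180,200,222,240,262,286,302
P8,102,120,140,160,186,206,226,246,262,282,302
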