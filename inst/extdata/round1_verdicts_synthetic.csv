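"item_id","status"
"1","SELECTED"
"2","UP_FOR_DISCUSSION"
"3","NOT_SELECTED"
"4","SELECTED"
"5","SELECTED"
"6","SELECTED"
"7","UP_FOR_DISCUSSION"
"8","UP_FOR_DISCUSSION"
"9","UP_FOR_DISCUSSION"
"10","SELECTED"
"11","UP_FOR_DISCUSSION"
"12.1","SELECTED"
"12.2","SELECTED"
"12.3","SELECTED"
"13","SELECTED"
"14.1","SELECTED"
"14.2","UP_FOR_DISCUSSION"
"14.3","SELECTED"
"14.4","UP_FOR_DISCUSSION"
"14.5","UP_FOR_DISCUSSION"
"15","SELECTED"
"16","SELECTED"
"17","SELECTED"
"18","SELECTED"
"19","UP_FOR_DISCUSSION"
"20","SELECTED"
"21.1","SELECTED"
"21.2","SELECTED"
"22","SELECTED"
"23.1","SELECTED"
"23.2","SELECTED"
"23.3","SELECTED"
"23.4","SELECTED"
"23.5","UP_FOR_DISCUSSION"
"23.6","SELECTED"
"23.7","UP_FOR_DISCUSSION"
"23.8","UP_FOR_DISCUSSION"
"24.1","UP_FOR_DISCUSSION"
"24.2","SELECTED"
"25","SELECTED"
"26","SELECTED"
"27.1","SELECTED"
"27.2","UP_FOR_DISCUSSION"
"27.3","SELECTED"
"27.4","SELECTED"
"27.5","UP_FOR_DISCUSSION"
"27.6","NOT_SELECTED"
"27.7","NOT_SELECTED"
"27.8","NOT_SELECTED"
"27.9","SELECTED"
"28","SELECTED"
"29","SELECTED"
"30","SELECTED"
"31","NOT_SELECTED"
"32","UP_FOR_DISCUSSION"
"33","NOT_SELECTED"
"34","NOT_SELECTED"
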