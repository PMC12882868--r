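>MYBrep_seed01
LKRGAWTEEEDAGLVDFVNKHGEGNWRVVAKRAGLKKCGKSCRLRWLNYLRP
>MYBrep_seed02
LKRGPWTEGEDQLLVDYVPKHGEGNWRAVAKRAGLKRKGKICRLRWLTYLRS
>MYBrep_seed03
LGRGPWTEEEDQLLVDYVNKHGEGNWRPVAKRAGLMRCGKSCRRRWLDYPRP
>MYBrep_seed04
LKRGPWTEPEDELLVDYVNLHGEGNWRAVACRAGIKGCGKSCRLRWLNYLRP
>MYBrep_seed05
LMRGPWTEEEDQLVVDYVNKHGEGNWRAVAKRAGLKWCPKSCILRWLNYKRP
>MYBrep_seed06
LKRGPWTEEEDQLPVDYVNKHGHGNWRAIAKRAGLKRCIKSCYGRWLNYLRP
>MYBrep_seed07
LKRGPWTEEETFLLCDYVNKHGEGNWTAVYKRAGLKQCGKSCRLRWLNYLRP
>MYBrep_seed08
LKRPHWTEEEDQLLVRYVQKHGEGNWRAVAKRAGLKRCGKSCILRWLNYLVP
>MYBrep_seed09
LTRGPWMEEEDQLLVDYVNKHGEGNWRAVALRHGLKRCYKSCRLRWLNYLKP
>MYBrep_seed10
CKRGPWTEEEQQLLVDYVNKHGEGNWRHVAKRAGLKFCQKSCRLRWLNPLRP
>MYBrep_seed11
LKRGPWTEEEDQLPVDYVNKKGCGNWRAVAKRACLKRCYKSCNLRWLNYLRP
>MYBrep_seed12
LKFGPWTAEDDQLLVDYWNKHGEGNWRYVAKRAGLKRCGKSHRLRWLNYLRP
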