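#n=50
#p=200
0.000000000000000
0.286621631835634
0.312922230878081
0.314269626125688
0.340821240613687
0.363222380063918
0.415184998086865
0.450677482587863
0.479124113648635
0.494001407257766
0.528194150905785
0.562310222670473
0.580348589911529
0.583897236505794
0.606444303936740
0.653408108554402
0.659717371834521
0.688436862403760
0.752925048428059
0.761491150208791
0.776836670538798
0.805807844436305
0.838174089328366
0.880210360007089
0.913416845602222
0.939164969583782
0.958295468061057
1.044506777031738
1.074970729768856
1.106709268783096
1.122430976014917
1.134973052029874
1.167846375812179
1.192542043926330
1.283716267603756
1.317279764164418
1.333069496850245
1.396367083764912
1.443392705119864
1.488658628545226
1.515601413191703
1.579185733336158
1.611241232869848
1.666441538496842
1.750696763613350
1.848764886748510
1.853056756038425
1.890562286014747
1.965631248174441
2.266430568084973
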