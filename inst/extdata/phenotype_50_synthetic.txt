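 2.38772182308
-0.36171852970
-2.07212005847
 0.67362455612
-0.09224710950
 0.36861055095
 0.51247639921
-2.74076666487
-1.73787852787
 0.93652136805
 0.45374314212
 1.88855172449
-0.01141037096
 3.15977797394
 3.05989953247
-2.36030111149
 3.39301786315
-0.02907182634
-3.12142301958
-1.59919081425
 1.33821287712
 0.89904250458
-0.43240588525
 2.03842940844
 0.16875328701
 2.67154578076
-1.50325832345
-2.16334339367
-0.79886179437
-0.13898352571
 1.27528795131
 1.17857271224
 0.53034480051
-0.40514612781
 0.60608029420
-1.05746881063
 0.53279830716
 0.66329466773
-0.60887324107
 0.43021640321
-0.89076708968
 0.40597349161
 2.68456712704
-0.43223891195
-0.94155583057
-0.29402412699
-1.11854008038
-0.96367416932
-0.11974122576
 0.25257309581
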