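drug	rate_se	indication_score
Nefazodone	0.33333	0.0794702
Milnacipran	0.62295879	0.1589404
Mianserin	0.34600026	0.1192
Trazodone	0.81612163	0.31788079
Nortriptyline	0.3283245	0.1589404
Duloxetine	0.99170246	0.91390728
Clomipramine	0.41045464	0.39735099
Reboxetine	0.36668174	0.47682119
Mirtazapine	0.59422385	0.95364238
Venlafaxine	0.81547802	1.43046358
Citalopram	0.92540653	1.82781457
Fluoxetine	0.86558296	5.16556291
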