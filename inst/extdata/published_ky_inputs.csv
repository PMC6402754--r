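season,irrigation,density,rel_et_deficit,rel_gy_decrease,ky_printed
1,0.75,150,0.224,0.501,2.23
1,0.75,250,0.222,0.228,1.02
1,0.75,350,0.217,0.145,0.67
1,0.75,450,0.216,0.233,1.08
1,0.75,550,0.216,0.341,1.58
1,0.50,150,0.437,0.624,1.43
1,0.50,250,0.436,0.477,1.10
1,0.50,350,0.436,0.520,1.19
1,0.50,450,0.435,0.579,1.33
1,0.50,550,0.434,0.656,1.51
2,0.75,150,0.224,0.466,2.08
2,0.75,250,0.222,0.237,1.07
2,0.75,350,0.214,0.128,0.59
2,0.75,450,0.217,0.266,1.13
2,0.75,550,0.214,0.312,1.46
2,0.50,150,0.432,0.590,1.37
2,0.50,250,0.434,0.462,1.06
2,0.50,350,0.430,0.524,1.22
2,0.50,450,0.429,0.555,1.29
2,0.50,550,0.428,0.595,1.39
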