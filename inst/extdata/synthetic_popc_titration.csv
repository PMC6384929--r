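quencher_conc_M,intensity
0.0000000000000000e+00,1.0077255991805812e+06
9.9999999999999995e-08,8.0181761985250982e+05
1.9999999999999999e-07,7.5482336671707290e+05
2.9999999999999999e-07,7.2150100588054582e+05
3.9999999999999998e-07,6.9691735898279771e+05
4.9999999999999998e-07,6.6597520749388763e+05
5.9999999999999997e-07,6.7529295716178394e+05
6.9999999999999997e-07,6.6590656605589588e+05
7.9999999999999996e-07,6.7217951957153587e+05
8.9999999999999996e-07,6.6220229680604849e+05
9.9999999999999995e-07,6.5951122390125820e+05
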