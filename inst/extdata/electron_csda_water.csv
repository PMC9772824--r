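energy_keV,csda_range_g_cm2
1,5.0e-06
2,1.54e-05
3,3.0e-05
4,4.9e-05
5,7.2e-05
6,9.8e-05
8,1.60e-04
10,2.52e-04
15,5.10e-04
20,8.57e-04
30,1.76e-03
40,2.92e-03
50,4.32e-03
60,5.94e-03
80,9.80e-03
100,1.43e-02
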