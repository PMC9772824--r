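element,Z,atomic_weight,K_edge_keV,K_fluorescence_yield,K_alpha_keV,KLL_auger_keV,K_shell_fraction
H,1,1.0079,0,0,0,0,0
Be,4,9.0122,0,0,0,0,0
C,6,12.0107,0,0,0,0,0
N,7,14.0067,0,0,0,0,0
O,8,15.9994,0,0,0,0,0
Na,11,22.9898,1.0721,0.023,1.041,0.994,0.9112
Mg,12,24.3050,1.305,0.03,1.2536,1.186,0.9224
P,15,30.9738,2.1455,0.063,2.0137,1.857,0.9104
S,16,32.0650,2.472,0.078,2.3078,2.117,0.9067
Cl,17,35.4530,2.8224,0.097,2.6224,2.381,0.9032
Ar,18,39.9480,3.2029,0.118,2.9577,2.66,0.8999
K,19,39.0983,3.6074,0.14,3.3138,2.987,0.8970
Ca,20,40.0780,4.0385,0.163,3.6917,3.313,0.8946
Fe,26,55.8450,7.112,0.347,6.3996,5.69,0.8816
Cu,29,63.5460,8.9789,0.441,8.041,7.127,0.8762
W,74,183.8400,69.525,0.958,58.87,47.3,0.8055
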