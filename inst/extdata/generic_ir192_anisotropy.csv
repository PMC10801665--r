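# Synthetic illustrative 1-D anisotropy function phi_an(r) for a generic
# high-energy HDR (Ir-192-like) point source. Generic smooth values, NOT
# consensus data for any commercial source.
r_mm,phi
1,0.920
2,0.940
5,0.955
10,0.960
20,0.965
30,0.968
40,0.970
50,0.972
60,0.973
80,0.975
100,0.976
150,0.978
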