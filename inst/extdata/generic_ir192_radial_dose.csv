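# Synthetic illustrative radial dose function g(r) for a generic high-energy
# HDR (Ir-192-like) point source. These are smooth generic values, NOT
# consensus data for any commercial source; use measured/consensus tables for
# clinical work. Normalized so g(r0 = 10 mm) = 1.
r_mm,g
1,0.990
2,0.994
5,0.998
10,1.000
20,1.001
30,1.000
40,0.997
50,0.992
60,0.985
80,0.966
100,0.940
150,0.850
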