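ATOM      1  CA  GLY B 101       2.585  -0.532  -4.050  1.00  0.00              
ATOM      2  CA  GLY B 102       1.450   1.818  -3.150  1.00  0.00              
ATOM      3  CA  GLY B 103      -1.096   2.390  -2.250  1.00  0.00              
ATOM      4  CA  GLY B 104      -3.127   0.751  -1.350  1.00  0.00              
ATOM      5  CA  GLY B 105      -3.105  -1.859  -0.450  1.00  0.00              
ATOM      6  CA  GLY B 106      -1.047  -3.464   0.450  1.00  0.00              
ATOM      7  CA  GLY B 107       1.489  -2.850   1.350  1.00  0.00              
ATOM      8  CA  GLY B 108       2.585  -0.481   2.250  1.00  0.00              
ATOM      9  CA  GLY B 109       1.410   1.849   3.150  1.00  0.00              
ATOM     10  CA  GLY B 110      -1.145   2.378   4.050  1.00  0.00              
END   
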