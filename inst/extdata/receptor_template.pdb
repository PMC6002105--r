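ATOM      1  CA  GLY A   1       9.997   0.000 -11.750  1.00  0.00              
ATOM      2  CA  GLY A   2      -7.353   6.736 -11.250  1.00  0.00              
ATOM      3  CA  GLY A   3       0.867  -9.884 -10.750  1.00  0.00              
ATOM      4  CA  GLY A   4       5.990   7.814 -10.250  1.00  0.00              
ATOM      5  CA  GLY A   5      -9.595  -1.697  -9.750  1.00  0.00              
ATOM      6  CA  GLY A   6       8.112  -5.160  -9.250  1.00  0.00              
ATOM      7  CA  GLY A   7      -2.455   9.133  -8.750  1.00  0.00              
ATOM      8  CA  GLY A   8      -4.273  -8.227  -8.250  1.00  0.00              
ATOM      9  CA  GLY A   9       8.503   3.105  -7.750  1.00  0.00              
ATOM     10  CA  GLY A  10      -8.134   3.358  -7.250  1.00  0.00              
ATOM     11  CA  GLY A  11       3.607  -7.709  -6.750  1.00  0.00              
ATOM     12  CA  GLY A  12       2.449   7.807  -6.250  1.00  0.00              
ATOM     13  CA  GLY A  13      -6.754  -3.914  -5.750  1.00  0.00              
ATOM     14  CA  GLY A  14       7.206  -1.584  -5.250  1.00  0.00              
ATOM     15  CA  GLY A  15      -3.961   5.634  -4.750  1.00  0.00              
ATOM     16  CA  GLY A  16      -0.812  -6.267  -4.250  1.00  0.00              
ATOM     17  CA  GLY A  17       4.321   3.642  -3.750  1.00  0.00              
ATOM     18  CA  GLY A  18      -4.837   0.200  -3.250  1.00  0.00              
ATOM     19  CA  GLY A  19       2.693  -2.680  -2.750  1.00  0.00              
ATOM     20  CA  GLY A  20      -0.103   2.220  -2.250  1.00  0.00              
END   
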