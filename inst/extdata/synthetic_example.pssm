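
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapped matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   V   Y   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   V   Y
    1 M    -3  -2  -1   0   1   2   3   4   5   6   7  -3  -2  -1   0   1   2   3   4   5    0   0   0   0   0   0   0   0   0  12   0   0  88   0   0   0   0   0   0   0  0.40 0.12
    2 K     7   6   5   4   3   2   1   0  -1  -2  -3   7   6   5   4   3   2   1   0  -1   25   0   0   0   0   0   0   0   0   0   0  75   0   0   0   0   0   0   0   0  0.52 0.18
    3 A     0   1   0  -1   2  -2   3  -3   4   0   5   1   6  -1   7   2   0   3  -2   4   50   0   0   0   0   0   0   0   0   0   0   0   0   0  50   0   0   0   0   0  0.31 0.09
    4 V     1   1   2   2   3   3   4   4   5   5  -1  -1  -2  -2   0   0   7   7  -3  -3    0   0   0   0   0   0   0   0  30  30   0   0   0   0   0   0   0  40   0   0  0.27 0.11

                      K         Lambda
Standard Ungapped    0.1347     0.3240
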