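
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
             A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V  A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
    1 M   -5   5  -4  -3   3   5  -2  -2   0  -8  -8   5   8  -7  -7   2  -2  -8  -1  -3   71  14  76  61  30  32  13  70  74  91  96  51  38  12  67  93  32   4  98  43   0.00      0.00
    2 A   -2   1  -4   1  -3  -3   2   4  -2   2  -6   8   0   7   8   7  -4  -6  -5   7   55  56  56  19  11   3  80  90   1  77  82  79  48  49  55  72  51  43  34  38   0.00      0.00
    3 K   -8  -2  -7   1  -2  -8   8   3   7   6   2  -6   8  -8  -7  -1   3   0   8  -7   70  37  70  28  92  52  81  49   2  36  89  33  96 100  24  74   3  34  19  28   0.00      0.00
    4 L   -7   0   1  -3   1  -1  -5   7   2   1  -8  -6   6   3   2   0   5  -3   0  -1   99  61  24  41  79  85  96  72  37  42  22  92  86  59  37  21  76  22  21  90   0.00      0.00
    5 V    2   6   3   6  -3  -3   4  -8   1   7   5  -2  -2  -2  -6   1  -3   8  -8   5   99   5  30  59  43  88  95  19  14  80  67  34  61  89  80  95  59  28  40  35   0.00      0.00
    6 S    5  -4   6   3   5   3  -1   4  -2   3  -3   5   6   0  -6   6   7  -4   1  -5   72   3  36  64  73  23  71  97  27   0  79  73  32  89  87   2  64  34  85  31   0.00      0.00
    7 T   -8   0  -8  -3  -7  -3   7  -3  -7  -2   0  -6   7   4   5  -4   6   0   5  -1   26  34  91  27  97  36  52 100  54  89  90  69  34  39  72  50  63  35  82  94   0.00      0.00
    8 K    1   5  -6  -1   4  -1   5   8   1  -1  -4   3  -5  -7   4  -4  -7   3   1  -4   40  98  27  77  25  14  55  92  68  44  56  59  10  33  44  18  52  72  17  50   0.00      0.00

                      K         Lambda
Standard Ungapped    0.1347     0.3176
Standard Gapped      0.0410     0.2670
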