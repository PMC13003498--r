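DMF
  nanosponge curated guest template

  5  4  0  0  0  0  0  0  0  0999 V2000
   -1.6673   -0.7891    0.0075 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4537   -0.0005   -0.0091 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5234    1.4466    0.0011 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7815   -0.6153   -0.0074 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8629   -0.0418    0.0079 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  4  5  2  0  0  0  0
M  END
$$$$
DEF
  nanosponge curated guest template

  7  6  0  0  0  0  0  0  0  0999 V2000
   -2.0934    0.7341    0.0068 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6774    1.2866   -0.0050 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3139    0.2203   -0.0134 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1320   -1.1686   -0.0082 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6480   -1.2822    0.0068 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6630    0.5139    0.0091 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5739   -0.3041    0.0039 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  3  6  1  0  0  0  0
  4  5  1  0  0  0  0
  6  7  2  0  0  0  0
M  END
$$$$
pyridine
  nanosponge curated guest template

  6  6  0  0  0  0  0  0  0  0999 V2000
   -1.3962    0.0014    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6924    1.2011   -0.0003 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6925    1.1487    0.0003 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4009   -0.0014   -0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.6900   -1.1501   -0.0003 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6949   -1.1997    0.0003 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  6  2  0  0  0  0
  2  3  2  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
M  END
$$$$
cyclohexane
  nanosponge curated guest template

  6  6  0  0  0  0  0  0  0  0999 V2000
    1.4431    0.2051    0.2276 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8981   -1.1454   -0.2306 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5421   -1.3502    0.2319 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4416   -0.2068   -0.2300 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9003    1.1456    0.2272 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5429    1.3517   -0.2261 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  6  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  1  0  0  0  0
M  END
$$$$
urea
  nanosponge curated guest template

  4  3  0  0  0  0  0  0  0  0999 V2000
   -1.1266   -0.6756    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0003    0.0611   -0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1320   -0.6667    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0051    1.2812    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  2  0  0  0  0
M  END
$$$$
Hmim
  nanosponge curated guest template

  6  6  0  0  0  0  0  0  0  0999 V2000
    2.1765   -0.0521   -0.0020 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6976    0.0235    0.0015 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0369    1.1164    0.0013 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3389    0.6901   -0.0010 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4006   -0.6818   -0.0016 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0977   -1.0961    0.0018 N   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  6  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
M  END
$$$$
benzoic acid
  nanosponge curated guest template

  9  9  0  0  0  0  0  0  0  0999 V2000
   -2.3230   -0.3220   -1.1402 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7845    0.0063    0.0536 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4446    0.3027    1.0333 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3032    0.0245    0.0359 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4116    1.2181   -0.1293 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8073    1.1923   -0.1431 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4855   -0.0196   -0.0041 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7730   -1.2108    0.1395 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3780   -1.1915    0.1546 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
  4  5  1  0  0  0  0
  4  9  2  0  0  0  0
  5  6  2  0  0  0  0
  6  7  1  0  0  0  0
  7  8  2  0  0  0  0
  8  9  1  0  0  0  0
M  END
$$$$
ethyl acetate
  nanosponge curated guest template

  6  5  0  0  0  0  0  0  0  0999 V2000
   -1.7742    0.6563   -0.1502 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4386   -0.8053    0.0800 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0197   -1.0103    0.0166 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.7363    0.1220    0.0264 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1870   -0.2261   -0.0954 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3092    1.2635    0.1226 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  4  6  2  0  0  0  0
M  END
$$$$
benzaldehyde
  nanosponge curated guest template

  8  8  0  0  0  0  0  0  0  0999 V2000
    2.8463    0.3891   -0.0102 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.0106   -0.5060    0.0075 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5599   -0.2307    0.0038 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3403   -1.3002    0.0002 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7128   -1.0453   -0.0036 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1799    0.2703   -0.0030 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2783    1.3356    0.0010 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0945    1.0872    0.0042 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  3  8  2  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
M  END
$$$$
isovaleraldehyde
  nanosponge curated guest template

  6  5  0  0  0  0  0  0  0  0999 V2000
   -1.3985   -0.8999    0.8457 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0600   -0.0629   -0.3908 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0223    1.4204   -0.0189 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2788   -0.4827   -1.0068 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3833   -0.4956    0.0196 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8188    0.5207    0.5513 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
M  END
$$$$
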