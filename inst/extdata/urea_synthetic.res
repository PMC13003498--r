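TITL synthetic-I2a-sponge
CELL 0.0251   10.8500   15.0000   22.3500   90.000   95.500   90.000
LATT -1
SYMM 1/2-X, Y, -Z
SYMM -X, -Y, -Z
SYMM 1/2+X, 1/2+Y, 1/2+Z
SYMM 1/2+X, -Y, Z
SYMM -X, 1/2+Y, 1/2-Z
SYMM 1/2-X, 1/2-Y, 1/2-Z
SYMM X, 1/2-Y, 1/2+Z
SFAC BI O C
UNIT 1 1 1
Bi1    1   0.362200   0.467100   0.117800   11.00000    0.02000
O1W    2   0.132300   0.416300   0.143400   11.00000    0.05000
O1     2   0.430000   0.311300   0.140100   11.00000    0.04000
C1     3   0.486000   0.225000   0.173000   11.00000    0.04000
Q1     2   0.328217   0.636581   0.295658   11.00000    0.05000      3.51
Q2     2   0.429110   0.616706   0.282384   11.00000    0.05000      3.30
Q3     2   0.253594   0.584886   0.327624   11.00000    0.05000      3.07
Q4     2   0.276399   0.718147   0.280404   11.00000    0.05000      2.44
HKLF 4
END
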