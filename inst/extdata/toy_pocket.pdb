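ATOM      1  N   ALA A   1      11.310   0.900   0.000  1.00  0.00           N  
ATOM      2  CA  ALA A   1      12.760   0.000   0.000  1.00  0.00           C  
ATOM      3  C   ALA A   1      11.860  -1.200   0.000  1.00  0.00           C  
ATOM      4  O   ALA A   1      10.810  -1.800   0.000  1.00  0.00           O  
ATOM      5  CB  ALA A   1      14.290   0.000   0.000  1.00  0.00           C  
ATOM      6  N   SER A   2       2.639  11.034   0.000  1.00  0.00           N  
ATOM      7  CA  SER A   2       3.943  12.135   0.000  1.00  0.00           C  
ATOM      8  C   SER A   2       4.806  10.908   0.000  1.00  0.00           C  
ATOM      9  O   SER A   2       5.052   9.724   0.000  1.00  0.00           O  
ATOM     10  CB  SER A   2       4.416  13.590   0.000  1.00  0.00           C  
ATOM     11  OG  SER A   2       3.449  14.661   0.000  1.00  0.00           O  
ATOM     12  N   ALA A   3      -9.679   5.920   0.000  1.00  0.00           N  
ATOM     13  CA  ALA A   3     -10.323   7.500   0.000  1.00  0.00           C  
ATOM     14  C   ALA A   3      -8.889   7.942   0.000  1.00  0.00           C  
ATOM     15  O   ALA A   3      -7.687   7.810   0.000  1.00  0.00           O  
ATOM     16  CB  ALA A   3     -11.561   8.399   0.000  1.00  0.00           C  
ATOM     17  N   ALA A   4      -8.621  -7.376   0.000  1.00  0.00           N  
ATOM     18  CA  ALA A   4     -10.323  -7.500   0.000  1.00  0.00           C  
ATOM     19  C   ALA A   4     -10.300  -6.000   0.000  1.00  0.00           C  
ATOM     20  O   ALA A   4      -9.803  -4.898   0.000  1.00  0.00           O  
ATOM     21  CB  ALA A   4     -11.561  -8.399   0.000  1.00  0.00           C  
ATOM     22  N   ALA A   5       4.351 -10.478   0.000  1.00  0.00           N  
ATOM     23  CA  ALA A   5       3.943 -12.135   0.000  1.00  0.00           C  
ATOM     24  C   ALA A   5       2.524 -11.650   0.000  1.00  0.00           C  
ATOM     25  O   ALA A   5       1.628 -10.837   0.000  1.00  0.00           O  
ATOM     26  CB  ALA A   5       4.416 -13.590   0.000  1.00  0.00           C  
HETATM   27  C1  LIG L   1      17.790   0.000   0.000  1.00  0.00           C  
HETATM   28  C2  LIG L   1      17.579  -1.192   0.105  1.00  0.00           C  
HETATM   29  C3  LIG L   1     -14.150  10.280   0.000  1.00  0.00           C  
HETATM   30  O4  LIG L   1       2.874  17.606   0.000  1.00  0.00           O  
END   
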