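HELIX    1   1 ALA A    1  ALA A    4  1                                   4
HELIX    2   2 ALA A    5  ALA A    7  1                                   3
ATOM      1  N   ALA A   1       1.000   0.800   0.100  1.00 20.00           N
ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00 20.00           C
ATOM      3  C   ALA A   1       2.100  -0.700   0.300  1.00 20.00           C
ATOM      4  O   ALA A   1       2.200  -1.200   1.200  1.00 20.00           O
ATOM      5  CB  ALA A   1       1.700   1.400  -0.900  1.00 20.00           C
ATOM      6  HB  ALA A   1       1.800   1.900  -1.400  1.00 20.00           H
ATOM      7  N   ALA A   2       2.500   0.800   0.100  1.00 20.00           N
ATOM      8  CA  ALA A   2       3.000   0.000   0.000  1.00 20.00           C
ATOM      9  C   ALA A   2       3.600  -0.700   0.300  1.00 20.00           C
ATOM     10  O   ALA A   2       3.700  -1.200   1.200  1.00 20.00           O
ATOM     11  CB AALA A   2       1.000   1.400  -0.900  0.30 20.00           C
ATOM     12  CB BALA A   2       4.500   1.400  -0.900  0.70 20.00           C
ATOM     13  HB  ALA A   2       3.300   1.900  -1.400  1.00 20.00           H
ATOM     14  N   ALA A   3       4.000   0.800   0.100  1.00 20.00           N
ATOM     15  CA  ALA A   3       4.500   0.000   0.000  1.00 20.00           C
ATOM     16  C   ALA A   3       5.100  -0.700   0.300  1.00 20.00           C
ATOM     17  O   ALA A   3       5.200  -1.200   1.200  1.00 20.00           O
ATOM     18  CB  ALA A   3       4.700   1.400  -0.900  1.00 20.00           C
ATOM     19  HB  ALA A   3       4.800   1.900  -1.400  1.00 20.00           H
ATOM     20  N   ALA A   4       5.500   0.800   0.100  1.00 20.00           N
ATOM     21  CA  ALA A   4       6.000   0.000   0.000  1.00 20.00           C
ATOM     22  C   ALA A   4       6.600  -0.700   0.300  1.00 20.00           C
ATOM     23  O   ALA A   4       6.700  -1.200   1.200  1.00 20.00           O
ATOM     24  CB  ALA A   4       6.200   1.400  -0.900  1.00 20.00           C
ATOM     25  HB  ALA A   4       6.300   1.900  -1.400  1.00 20.00           H
ATOM     26  N   ALA A   5       7.000   5.800   0.100  1.00 20.00           N
ATOM     27  CA  ALA A   5       7.500   5.000   0.000  1.00 20.00           C
ATOM     28  C   ALA A   5       8.100   4.300   0.300  1.00 20.00           C
ATOM     29  O   ALA A   5       8.200   3.800   1.200  1.00 20.00           O
ATOM     30  CB  ALA A   5       7.700   6.400  -0.900  1.00 20.00           C
ATOM     31  HB  ALA A   5       7.800   6.900  -1.400  1.00 20.00           H
ATOM     32  N   ALA A   6       8.500   5.800   0.100  1.00 20.00           N
ATOM     33  CA  ALA A   6       9.000   5.000   0.000  1.00 20.00           C
ATOM     34  C   ALA A   6       9.600   4.300   0.300  1.00 20.00           C
ATOM     35  O   ALA A   6       9.700   3.800   1.200  1.00 20.00           O
ATOM     36  CB  ALA A   6       9.200   6.400  -0.900  1.00 20.00           C
ATOM     37  HB  ALA A   6       9.300   6.900  -1.400  1.00 20.00           H
ATOM     38  N   ALA A   7      10.000   5.800   0.100  1.00 20.00           N
ATOM     39  CA  ALA A   7      10.500   5.000   0.000  1.00 20.00           C
ATOM     40  C   ALA A   7      11.100   4.300   0.300  1.00 20.00           C
ATOM     41  O   ALA A   7      11.200   3.800   1.200  1.00 20.00           O
ATOM     42  CB  ALA A   7      10.700   6.400  -0.900  1.00 20.00           C
ATOM     43  HB  ALA A   7      10.800   6.900  -1.400  1.00 20.00           H
END
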