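ATOM      1  N   ALA A   1       1.301  -0.663  -0.900  1.00  0.00           N
ATOM      2  CA  ALA A   1       2.300   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       1.483   0.723   1.050  1.00  0.00           C
ATOM      4  O   ALA A   1       1.696   1.060   2.200  1.00  0.00           O
ATOM      5  CB  ALA A   1       3.250  -0.573  -0.450  1.00  0.00           C
ATOM      6  N   ALA A   2       0.427   1.396   0.600  1.00  0.00           N
ATOM      7  CA  ALA A   2      -0.399   2.265   1.500  1.00  0.00           C
ATOM      8  C   ALA A   2      -0.970   1.335   2.550  1.00  0.00           C
ATOM      9  O   ALA A   2      -1.338   1.486   3.700  1.00  0.00           O
ATOM     10  CB  ALA A   2       0.000   3.300   1.050  1.00  0.00           C
ATOM     11  N   ALA A   3      -1.449   0.178   2.100  1.00  0.00           N
ATOM     12  CA  ALA A   3      -2.161  -0.787   3.000  1.00  0.00           C
ATOM     13  C   ALA A   3      -1.146  -1.187   4.050  1.00  0.00           C
ATOM     14  O   ALA A   3      -1.231  -1.576   5.200  1.00  0.00           O
ATOM     15  CB  ALA A   3      -3.250  -0.573   2.550  1.00  0.00           C
ATOM     16  N   ALA A   4       0.076  -1.458   3.600  1.00  0.00           N
ATOM     17  CA  ALA A   4       1.150  -1.992   4.500  1.00  0.00           C
ATOM     18  C   ALA A   4       1.368  -0.923   5.550  1.00  0.00           C
ATOM     19  O   ALA A   4       1.766  -0.939   6.700  1.00  0.00           O
ATOM     20  CB  ALA A   4       1.129  -3.101   4.050  1.00  0.00           C
ATOM     21  N   ALA A   5       1.423   0.328   5.100  1.00  0.00           N
ATOM     22  CA  ALA A   5       1.762   1.478   6.000  1.00  0.00           C
ATOM     23  C   ALA A   5       0.671   1.507   7.050  1.00  0.00           C
ATOM     24  O   ALA A   5       0.618   1.902   8.200  1.00  0.00           O
ATOM     25  CB  ALA A   5       2.858   1.650   5.550  1.00  0.00           C
ATOM     26  N   ALA A   6      -0.570   1.344   6.600  1.00  0.00           N
ATOM     27  CA  ALA A   6      -1.762   1.478   7.500  1.00  0.00           C
ATOM     28  C   ALA A   6      -1.601   0.399   8.550  1.00  0.00           C
ATOM     29  O   ALA A   6      -1.981   0.278   9.700  1.00  0.00           O
ATOM     30  CB  ALA A   6      -2.121   2.528   7.050  1.00  0.00           C
ATOM     31  N   ALA A   7      -1.224  -0.795   8.100  1.00  0.00           N
ATOM     32  CA  ALA A   7      -1.150  -1.992   9.000  1.00  0.00           C
ATOM     33  C   ALA A   7      -0.115  -1.646  10.050  1.00  0.00           C
ATOM     34  O   ALA A   7       0.070  -1.999  11.200  1.00  0.00           O
ATOM     35  CB  ALA A   7      -2.121  -2.528   8.550  1.00  0.00           C
ATOM     36  N   ALA A   8       0.996  -1.068   9.600  1.00  0.00           N
ATOM     37  CA  ALA A   8       2.161  -0.787  10.500  1.00  0.00           C
ATOM     38  C   ALA A   8       1.641   0.172  11.550  1.00  0.00           C
ATOM     39  O   ALA A   8       1.956   0.416  12.700  1.00  0.00           O
ATOM     40  CB  ALA A   8       2.858  -1.650  10.050  1.00  0.00           C
ATOM     41  N   ALA B   1       9.153  -0.663  -0.900  1.00  0.00           N
ATOM     42  CA  ALA B   1       8.154   0.000   0.000  1.00  0.00           C
ATOM     43  C   ALA B   1       8.971   0.723   1.050  1.00  0.00           C
ATOM     44  O   ALA B   1       8.758   1.060   2.200  1.00  0.00           O
ATOM     45  CB  ALA B   1       7.249  -0.474  -0.450  1.00  0.00           C
ATOM     46  N   ALA B   2      10.027   1.396   0.600  1.00  0.00           N
ATOM     47  CA  ALA B   2      10.853   2.265   1.500  1.00  0.00           C
ATOM     48  C   ALA B   2      11.424   1.335   2.550  1.00  0.00           C
ATOM     49  O   ALA B   2      11.792   1.486   3.700  1.00  0.00           O
ATOM     50  CB  ALA B   2      10.444   3.293   1.050  1.00  0.00           C
ATOM     51  N   ALA B   3      11.903   0.178   2.100  1.00  0.00           N
ATOM     52  CA  ALA B   3      12.615  -0.787   3.000  1.00  0.00           C
ATOM     53  C   ALA B   3      11.600  -1.187   4.050  1.00  0.00           C
ATOM     54  O   ALA B   3      11.685  -1.576   5.200  1.00  0.00           O
ATOM     55  CB  ALA B   3      13.624  -0.552   2.550  1.00  0.00           C
ATOM     56  N   ALA B   4      10.377  -1.458   3.600  1.00  0.00           N
ATOM     57  CA  ALA B   4       9.304  -1.992   4.500  1.00  0.00           C
ATOM     58  C   ALA B   4       9.086  -0.923   5.550  1.00  0.00           C
ATOM     59  O   ALA B   4       8.688  -0.939   6.700  1.00  0.00           O
ATOM     60  CB  ALA B   4       9.382  -3.052   4.050  1.00  0.00           C
ATOM     61  N   ALA B   5       9.031   0.328   5.100  1.00  0.00           N
ATOM     62  CA  ALA B   5       8.692   1.478   6.000  1.00  0.00           C
ATOM     63  C   ALA B   5       9.783   1.507   7.050  1.00  0.00           C
ATOM     64  O   ALA B   5       9.836   1.902   8.200  1.00  0.00           O
ATOM     65  CB  ALA B   5       7.600   1.630   5.550  1.00  0.00           C
ATOM     66  N   ALA B   6      11.024   1.344   6.600  1.00  0.00           N
ATOM     67  CA  ALA B   6      12.216   1.478   7.500  1.00  0.00           C
ATOM     68  C   ALA B   6      12.055   0.399   8.550  1.00  0.00           C
ATOM     69  O   ALA B   6      12.434   0.278   9.700  1.00  0.00           O
ATOM     70  CB  ALA B   6      12.568   2.476   7.050  1.00  0.00           C
ATOM     71  N   ALA B   7      11.678  -0.795   8.100  1.00  0.00           N
ATOM     72  CA  ALA B   7      11.604  -1.992   9.000  1.00  0.00           C
ATOM     73  C   ALA B   7      10.569  -1.646  10.050  1.00  0.00           C
ATOM     74  O   ALA B   7      10.384  -1.999  11.200  1.00  0.00           O
ATOM     75  CB  ALA B   7      12.539  -2.439   8.550  1.00  0.00           C
ATOM     76  N   ALA B   8       9.458  -1.068   9.600  1.00  0.00           N
ATOM     77  CA  ALA B   8       8.292  -0.787  10.500  1.00  0.00           C
ATOM     78  C   ALA B   8       8.813   0.172  11.550  1.00  0.00           C
ATOM     79  O   ALA B   8       8.497   0.416  12.700  1.00  0.00           O
ATOM     80  CB  ALA B   8       7.608  -1.766  10.050  1.00  0.00           C
END
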