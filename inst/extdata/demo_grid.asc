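ncols 20
nrows 20
xllcorner -16.73684
yllcorner 5.263158
cellsize 1.473684
NODATA_value -9999
0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 100 0
0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
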