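date,class,area_km2
1995,cropland,69066.83
1995,forest,93458.77
1995,grassland,7542.89
1995,water,9797.99
1995,wetland,1027.49
1995,bare,51.77
1995,built_up,4954.25
2000,cropland,69425.6
2000,forest,92660.73
2000,grassland,7541.91
2000,water,9619.07
2000,wetland,1663.92
2000,bare,47.8
2000,built_up,4940.98
2005,cropland,68603.72
2005,forest,92591.53
2005,grassland,7506.02
2005,water,10437.53
2005,wetland,1513.55
2005,bare,46.8
2005,built_up,5200.84
2010,cropland,68234.93
2010,forest,92534.27
2010,grassland,7486.07
2010,water,10435.48
2010,wetland,1613.12
2010,bare,47.8
2010,built_up,5548.33
2015,cropland,67019.47
2015,forest,92167.33
2015,grassland,7450.26
2015,water,10499.27
2015,wetland,1612.13
2015,bare,48.79
2015,built_up,7102.74
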