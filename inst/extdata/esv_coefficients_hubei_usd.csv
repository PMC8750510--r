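class,function,service,value
cropland,FP,provisioning,394.96
cropland,RMP,provisioning,118.49
cropland,WS,provisioning,-31.6
cropland,GR,regulating,185.63
cropland,CR,regulating,142.18
cropland,PE,regulating,43.45
cropland,HR,regulating,434.45
cropland,SC,supporting,233.03
cropland,MNS,supporting,51.34
cropland,MB,supporting,47.39
cropland,AL,cultural,23.7
forest,FP,provisioning,98.74
forest,RMP,provisioning,229.08
forest,WS,provisioning,118.49
forest,GR,regulating,753.38
forest,CR,regulating,2254.22
forest,PE,regulating,660.57
forest,HR,regulating,1475.17
forest,SC,supporting,917.29
forest,MNS,supporting,70.11
forest,MB,supporting,835.34
forest,AL,cultural,366.32
grassland,FP,provisioning,90.84
grassland,RMP,provisioning,135.6
grassland,WS,provisioning,75.04
grassland,GR,regulating,476.58
grassland,CR,regulating,1259.92
grassland,PE,regulating,416.02
grassland,HR,regulating,922.89
grassland,SC,supporting,580.59
grassland,MNS,supporting,44.76
grassland,MB,supporting,527.93
grassland,AL,cultural,233.03
wetland,FP,provisioning,201.43
wetland,RMP,provisioning,197.48
wetland,WS,provisioning,1022.94
wetland,GR,regulating,750.42
wetland,CR,regulating,1421.85
wetland,PE,regulating,1421.85
wetland,HR,regulating,9569.84
wetland,SC,supporting,912.35
wetland,MNS,supporting,71.09
wetland,MB,supporting,3108.32
wetland,AL,cultural,1868.15
bare,FP,provisioning,1.97
bare,RMP,provisioning,5.92
bare,WS,provisioning,3.95
bare,GR,regulating,25.67
bare,CR,regulating,19.75
bare,PE,regulating,80.97
bare,HR,regulating,47.39
bare,SC,supporting,29.62
bare,MNS,supporting,1.97
bare,MB,supporting,27.65
bare,AL,cultural,11.85
water,FP,provisioning,244.87
water,RMP,provisioning,82.94
water,WS,provisioning,2812.1
water,GR,regulating,339.66
water,CR,regulating,663.53
water,PE,regulating,1129.58
water,HR,regulating,21600.27
water,SC,supporting,185.63
water,MNS,supporting,13.82
water,MB,supporting,1295.46
water,AL,cultural,548.99
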