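Program,xPONENT
Build,3.1.871.0
Date,01/09/2026,10:42:15
SN,SYNTH-0001
Batch,synthetic_demo_plate
Operator,demo
ProtocolName,synthetic_cytokine_panel
SampleVolume,50 uL

DataType:,Median
Location,Sample,IL6,TNFa,Total Events
"1(1,A1)",Standard1,1479.3,2099.8,102
"1(1,A2)",Standard2,1586.4,2959.9,95
"1(1,A3)",Standard3,1324.5,2172.9,103
"1(1,A4)",Standard4,1339.8,2108.4,113
"1(1,A5)",Standard5,1769.4,1740.9,101
"1(1,A6)",Standard6,1342.7,1864.4,108
"1(1,A7)",Standard7,1617.9,1456.2,103
"1(1,A8)",Standard8,1271.3,920.1,103
"1(1,A9)",Standard9,845.6,503.5,98
"1(1,A10)",Standard10,414.3,222.0,102
"1(1,A11)",Standard11,173.0,75.2,93
"1(1,A12)",Standard12,68.3,31.7,104
"1(1,B1)",Standard13,27.1,19.1,104
"1(1,B2)",Standard14,19.4,14.9,100
"1(1,B3)",Standard15,13.6,12.1,95
"1(1,B4)",Standard16,13.9,10.2,95
"1(1,B5)",Standard1,1543.3,2855.3,100
"1(1,B6)",Background1,13.9,10.4,98
"1(1,B7)",Background2,11.8,10.6,101
"1(1,B8)",S1,117.8,264.8,92
"1(1,B9)",S2,22.4,244.8,105
"1(1,B10)",S3,112.8,1144.9,103
"1(1,B11)",S4,76.7,890.4,102
"1(1,B12)",S5,983.9,2383.2,91
"1(1,C1)",S6,1313.2,34.2,102

DataType:,Count
Location,Sample,IL6,TNFa,Total Events
"1(1,A1)",Standard1,50,52,102
"1(1,A2)",Standard2,51,44,95
"1(1,A3)",Standard3,52,51,103
"1(1,A4)",Standard4,58,55,113
"1(1,A5)",Standard5,47,54,101
"1(1,A6)",Standard6,52,56,108
"1(1,A7)",Standard7,52,51,103
"1(1,A8)",Standard8,52,51,103
"1(1,A9)",Standard9,48,50,98
"1(1,A10)",Standard10,56,46,102
"1(1,A11)",Standard11,52,41,93
"1(1,A12)",Standard12,53,51,104
"1(1,B1)",Standard13,54,50,104
"1(1,B2)",Standard14,47,53,100
"1(1,B3)",Standard15,43,52,95
"1(1,B4)",Standard16,45,50,95
"1(1,B5)",Standard1,46,54,100
"1(1,B6)",Background1,49,49,98
"1(1,B7)",Background2,48,53,101
"1(1,B8)",S1,48,44,92
"1(1,B9)",S2,53,52,105
"1(1,B10)",S3,54,49,103
"1(1,B11)",S4,52,50,102
"1(1,B12)",S5,46,45,91
"1(1,C1)",S6,52,50,102

DataType:,Net MFI
Location,Sample,IL6,TNFa,Total Events
"1(1,A1)",Standard1,1469.8,2090.3,102
"1(1,A2)",Standard2,1576.9,2950.4,95
"1(1,A3)",Standard3,1315.0,2163.4,103
"1(1,A4)",Standard4,1330.3,2098.9,113
"1(1,A5)",Standard5,1759.9,1731.4,101
"1(1,A6)",Standard6,1333.2,1854.9,108
"1(1,A7)",Standard7,1608.4,1446.7,103
"1(1,A8)",Standard8,1261.8,910.6,103
"1(1,A9)",Standard9,836.1,494.0,98
"1(1,A10)",Standard10,404.8,212.5,102
"1(1,A11)",Standard11,163.5,65.7,93
"1(1,A12)",Standard12,58.8,22.2,104
"1(1,B1)",Standard13,17.6,9.6,104
"1(1,B2)",Standard14,9.9,5.4,100
"1(1,B3)",Standard15,4.1,2.6,95
"1(1,B4)",Standard16,4.4,0.7,95
"1(1,B5)",Standard1,1533.8,2845.8,100
"1(1,B6)",Background1,4.4,0.9,98
"1(1,B7)",Background2,2.3,1.1,101
"1(1,B8)",S1,108.3,255.3,92
"1(1,B9)",S2,12.9,235.3,105
"1(1,B10)",S3,103.3,1135.4,103
"1(1,B11)",S4,67.2,880.9,102
"1(1,B12)",S5,974.4,2373.7,91
"1(1,C1)",S6,1303.7,24.7,102

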