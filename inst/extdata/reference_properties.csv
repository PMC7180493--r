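des_id,tc_k,pc_bar,vc_cm3_mol,omega,mw_g_mol
DES1,670.98,36.65,355.99,0.6660,118.44
DES2,651.23,39.77,308.96,0.7476,104.34
DES3,632.35,43.77,264.25,0.8293,90.25
DES4,657.28,31.24,364.48,0.9659,124.53
DES5,720.58,25.62,480.62,0.9994,157.57
DES6,778.21,22.07,589.83,1.0507,190.61
DES7,749.11,25.67,433.69,1.3146,147.05
DES8,618.43,41.08,270.56,0.8745,92.97
DES9,678.15,31.88,377.22,0.9080,126.01
DES10,733.31,26.60,478.88,0.9593,159.05
DES11,708.07,32.89,333.89,1.2232,115.49
DES12,701.16,37.82,380.25,0.5152,138.05
DES13,644.10,33.78,334.18,0.9375,114.02
DES14,721.27,33.15,384.56,0.9166,135.02
DES15,735.27,27.58,401.61,1.2862,136.53
DES16,668.50,44.09,281.96,0.7863,99.10
DES17,683.07,47.23,259.82,0.8755,94.59
DES18,701.24,38.94,356.12,0.6195,116.46
DES19,637.98,61.84,206.94,0.5794,75.08
DES20,659.71,92.43,146.46,0.5139,59.39
DES21,644.44,49.54,254.37,0.6509,86.58
DES22,602.00,40.99,259.67,0.9155,87.92
DES23,680.67,33.46,315.17,1.2254,107.94
DES24,742.22,27.03,424.87,1.2278,153.13
DES25,738.99,27.23,422.14,1.2163,153.13
DES26,620.93,38.44,284.11,0.9290,91.98
DES27,702.19,35.40,376.78,0.7301,123.95
DES28,689.82,37.16,335.84,0.8577,121.84
DES29,713.43,32.24,397.17,0.8782,135.87
DES30,676.24,40.44,303.06,0.8531,114.83
DES31,737.07,24.71,559.27,0.7649,158.24
DES32,773.88,21.55,656.40,0.8307,181.61
DES33,717.72,28.79,493.39,0.6173,150.24
DES34,739.17,26.26,549.11,0.6568,164.27
DES35,744.23,33.56,445.77,0.5733,152.64
DES36,777.87,31.66,504.89,0.5094,168.94
DES37,654.33,38.54,319.91,0.7510,109.17
DES38,745.61,42.88,333.41,0.7044,115.78
DES39,721.95,48.54,272.60,0.8243,102.61
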