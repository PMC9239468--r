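subject_id,image_id,x,y,cell_type,mhcii
p01,a,128.34999999999999,134.84,tumor,1.982
p01,a,272.14999999999998,252.66999999999999,tumor,1.2090000000000001
p01,a,279.26999999999998,33.090000000000003,tumor,1.869
p01,a,182.80000000000001,258.95999999999998,stroma,0.88
p01,a,280.56999999999999,39.32,tumor,1.2689999999999999
p01,a,166.28,88.629999999999995,stroma,0.39600000000000002
p01,a,121.28,14.18,stroma,0.93200000000000005
p01,a,350.63999999999999,33.600000000000001,stroma,1.508
p01,a,47.619999999999997,204.13,stroma,0.29099999999999998
p01,a,360.75,255,stroma,0.93600000000000005
p01,a,381.24000000000001,239.19999999999999,stroma,0.42199999999999999
p01,a,281.42000000000002,87.689999999999998,tumor,0.82299999999999995
p01,a,206.31,184.56999999999999,stroma,0.73799999999999999
p01,b,287.52999999999997,66.120000000000005,tumor,1.0469999999999999
p01,b,123.56,57.439999999999998,tumor,1.75
p01,b,114.90000000000001,73.609999999999999,tumor,0.40200000000000002
p01,b,260.63,149.44,stroma,1.6679999999999999
p01,b,79.379999999999995,5.29,tumor,1.2
p01,b,252.83000000000001,206.94999999999999,stroma,0.44400000000000001
p01,b,177.59999999999999,144.87,tumor,2.1829999999999998
p01,b,124.93000000000001,292.72000000000003,stroma,0.56200000000000006
p01,b,283.41000000000003,92.370000000000005,stroma,0.68100000000000005
p01,b,113.63,34.700000000000003,stroma,0.40000000000000002
p01,b,14.359999999999999,257.63,stroma,0.496
p01,b,266.31999999999999,165.56999999999999,tumor,0.27500000000000002
p02,a,398.12,139.21000000000001,tumor,1.4019999999999999
p02,a,179.49000000000001,184.90000000000001,tumor,1.71
p02,a,5.7000000000000002,298.33999999999997,tumor,1.234
p02,a,9.1999999999999993,159,stroma,0.24099999999999999
p02,a,178.87,78.230000000000004,stroma,1.1279999999999999
p02,a,305.02999999999997,173.33000000000001,tumor,2.407
p02,a,271.81999999999999,113.70999999999999,stroma,1.4830000000000001
p02,a,275.41000000000003,113.17,tumor,4.5419999999999998
p02,a,36.950000000000003,132.83000000000001,tumor,1.48
p02,a,6.8200000000000003,276.72000000000003,tumor,0.503
p02,a,240.22,54.420000000000002,stroma,0.314
p02,a,348.42000000000002,225.84999999999999,tumor,0.432
p02,a,140.11000000000001,131.16999999999999,stroma,0.35799999999999998
p02,a,45.390000000000001,44.829999999999998,tumor,0.97099999999999997
p02,b,394.56,138.41,stroma,2.5009999999999999
p02,b,12.140000000000001,262.76999999999998,tumor,0.34899999999999998
p02,b,268.02999999999997,135.30000000000001,tumor,0.86899999999999999
p02,b,47.890000000000001,86.150000000000006,stroma,0.52700000000000002
p02,b,340.63,242.11000000000001,stroma,1.7430000000000001
p02,b,14.859999999999999,38.280000000000001,stroma,1.6359999999999999
p02,b,220,43.520000000000003,tumor,0.52600000000000002
p02,b,162.65000000000001,29.379999999999999,stroma,1.0129999999999999
p02,b,41.159999999999997,167.09999999999999,tumor,0.878
p02,b,335.20999999999998,260.89999999999998,tumor,0.72699999999999998
p02,b,258.37,149,stroma,0.19700000000000001
p02,b,356.98000000000002,72.5,tumor,0.39800000000000002
p02,b,168.36000000000001,259.20999999999998,stroma,1.4219999999999999
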