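batch_id,species,hypoxanthine,xanthine,uridine,inosine,guanosine,adenosine
1,Pheretima aspergillum,334.94,74.97,273.31,1385.52,238.03,NA
2,Pheretima aspergillum,269.84,51.37,430.44,1175.64,410.54,NA
3,Pheretima aspergillum,376.88,74.31,141.95,1366.53,173.45,NA
4,Pheretima aspergillum,151.97,38.56,155.30,1423.28,205.11,NA
5,Pheretima aspergillum,490.59,119.86,200.78,1488.43,209.50,NA
6,Pheretima aspergillum,451.66,88.54,168.29,1516.16,101.66,NA
7,Pheretima aspergillum,747.13,420.25,187.03,794.49,315.79,NA
8,Pheretima aspergillum,865.09,335.33,426.43,1847.55,378.55,NA
9,Pheretima aspergillum,651.40,71.06,213.91,1996.62,176.21,NA
10,Pheretima aspergillum,982.11,151.05,217.82,1428.58,57.85,NA
11,Pheretima aspergillum,361.08,85.21,101.72,856.37,73.14,NA
12,Pheretima aspergillum,587.68,108.87,341.48,955.73,217.59,NA
13,Pheretima aspergillum,131.05,36.01,88.29,1105.76,106.25,NA
14,Pheretima aspergillum,341.48,80.45,166.16,1140.47,184.39,NA
15,Pheretima aspergillum,652.87,206.48,427.23,1662.41,392.39,NA
16,Pheretima aspergillum,388.01,80.66,198.20,2590.25,195.38,NA
17,Pheretima aspergillum,292.67,31.51,49.08,1201.00,55.18,NA
18,Pheretima aspergillum,746.62,177.75,144.00,1510.70,132.25,NA
19,Pheretima aspergillum,457.21,89.50,95.54,1158.45,50.27,NA
20,Pheretima aspergillum,810.69,405.37,102.30,1143.91,120.23,NA
21,Pheretima aspergillum,513.11,160.13,220.05,2692.14,343.90,NA
22,Pheretima aspergillum,583.76,256.93,287.95,1932.09,203.00,NA
23,Amynthas obscuritoporus,503.07,82.11,143.20,991.91,84.55,819.37
24,Amynthas obscuritoporus,161.59,33.43,74.94,128.67,106.76,1119.98
25,Amynthas obscuritoporus,823.42,183.93,282.30,476.84,52.70,1357.74
26,Amynthas obscuritoporus,377.43,137.69,145.07,1220.17,106.53,852.75
27,Amynthas obscuritoporus,267.40,47.69,70.22,736.72,60.14,622.20
28,Amynthas obscuritoporus,40.71,20.03,53.53,715.92,69.21,1107.87
29,Amynthas obscuritoporus,300.54,69.96,70.89,302.82,48.73,303.92
30,Amynthas obscuritoporus,85.15,38.27,98.16,601.35,111.02,694.25
31,Amynthas obscuritoporus,138.46,72.34,115.70,1332.21,154.79,942.89
32,Metaphire magna,761.36,347.88,195.97,1103.22,187.11,128.88
33,Metaphire magna,601.76,58.22,152.63,885.40,87.35,139.22
34,Metaphire magna,332.29,64.13,131.00,1408.52,99.75,187.41
35,Metaphire magna,1018.72,328.83,151.43,191.79,860.87,135.63
36,Metaphire magna,171.51,40.68,128.51,1998.76,142.54,327.79
37,Metaphire magna,1050.56,876.82,139.77,2385.55,144.69,172.89
38,Metaphire magna,379.26,119.97,187.83,2324.06,127.85,398.14
39,Metaphire magna,150.83,18.61,97.10,1219.21,121.30,243.59
40,Metaphire magna,257.21,49.66,213.59,2029.20,168.91,197.30
41,Metaphire magna,110.27,31.60,202.07,2012.29,143.99,239.67
42,Metaphire magna,682.15,188.19,248.04,1378.25,142.54,275.75
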