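seal,mass_kg,standard_length_cm,girth_cm,flipper_cm,axis_cm,age_y,bathymetry,complexity,colony,coast,pipes_cables,wells,shipwrecks,foraging_cells,auc,structure_top
1,86.5,159.0,106.0,42.0,62.0,13,0.6,0.0,48.6,6.3,16.4,23.9,4.2,122,0.98,FALSE
2,91.5,165.0,110.5,43.5,72.5,12,4.5,0.3,6.6,37.1,16.2,25.8,9.5,14,0.99,TRUE
3,77.0,156.5,95.0,45.0,60.5,8,0.5,3.6,5.1,54.0,8.1,18.8,9.9,51,0.99,FALSE
4,82.0,161.5,105.0,47.5,65.0,8,0.7,0.1,18.8,13.2,31.4,22.4,13.5,57,0.98,TRUE
5,75.0,152.5,104.0,39.5,61.5,10,0.0,0.3,6.2,67.0,14.2,6.8,5.6,11,0.99,FALSE
6,59.0,142.5,97.5,41.0,61.5,4,8.6,26.8,26.1,29.8,0.0,8.6,0.1,11,0.93,FALSE
7,90.0,160.0,106.5,43.5,66.5,NA,2.7,0.0,67.7,9.3,2.4,13.6,4.3,31,0.98,FALSE
8,86.5,155.0,101.0,42.5,61.0,NA,1.4,0.2,4.5,72.1,9.2,4.2,8.4,57,0.98,FALSE
9,91.0,160.5,112.5,41.0,64.5,NA,20.6,0.0,5.7,61.2,11.6,0.9,0.0,8,0.92,FALSE
10,89.0,160.0,110.5,43.5,69.0,12,7.6,0.0,61.6,3.3,14.6,6.1,6.9,9,0.99,FALSE
11,84.0,157.0,106.0,48.5,64.5,NA,0.0,0.3,0.0,5.8,58.1,6.1,29.7,29,0.95,TRUE
12,71.0,149.0,93.5,39.0,58.0,5,0.0,22.0,49.2,19.9,4.2,1.9,2.8,21,0.99,FALSE
13,59.0,142.0,96.0,41.0,62.5,4,3.2,17.3,2.4,40.7,16.9,13.7,5.8,37,0.99,FALSE
14,67.0,146.5,97.5,41.0,63.5,5,1.5,1.9,9.3,39.2,19.6,6.8,21.7,27,0.99,FALSE
15,69.0,142.0,102.5,39.0,62.0,4,11.3,13.1,42.6,5.3,5.0,20.1,2.5,17,0.99,FALSE
16,81.0,151.5,103.0,42.5,64.0,6,0.2,0.0,6.0,20.3,25.6,47.6,0.4,193,0.99,TRUE
17,72.0,154.5,100.5,44.5,69.5,8,1.3,25.3,18.5,18.1,23.3,4.8,8.9,32,0.99,FALSE
18,91.5,159.0,118.5,45.5,68.0,7,0.6,0.0,62.9,22.4,10.7,0.4,3.0,34,0.99,FALSE
19,80.0,150.0,106.0,41.5,72.5,12,2.5,0.1,30.0,40.3,15.2,6.5,5.4,37,0.99,FALSE
20,63.5,146.5,98.5,40.5,64.5,6,0.0,0.0,2.6,56.9,30.1,0.4,10.0,54,0.97,FALSE
21,77.0,149.5,109.5,42.5,68.0,NA,2.6,9.6,37.9,37.2,9.6,0.3,2.8,25,0.99,FALSE
22,81.5,156.5,112.0,43.5,66.5,10,1.0,0.0,16.5,27.9,53.9,0.7,0.0,15,0.99,TRUE
23,55.0,139.5,93.5,40.5,59.0,NA,0.0,1.7,20.0,45.8,7.4,17.7,7.4,27,0.99,FALSE
24,86.5,160.0,116.0,43.0,68.5,11,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
25,51.0,135.0,89.5,40.0,58.5,4,0.0,0.0,0.3,0.3,39.6,59.5,0.4,17,0.99,TRUE
26,56.0,139.0,95.5,41.5,65.5,8,2.0,1.0,79.0,9.9,6.6,0.0,1.5,29,0.99,FALSE
27,62.5,147.5,95.5,43.5,60.0,4,NA,NA,NA,NA,NA,NA,NA,NA,NA,FALSE
28,101.0,154.5,119.5,44.0,73.0,NA,2.0,0.2,28.1,4.8,8.3,36.7,20.0,15,0.95,TRUE
29,71.0,144.5,98.0,41.5,64.0,7,1.3,0.3,0.7,43.0,18.3,16.1,20.3,80,0.90,TRUE
30,63.5,145.0,92.0,42.0,61.0,NA,7.5,2.2,44.5,28.3,14.4,1.0,2.1,45,0.94,FALSE
31,84.5,158.0,103.0,45.0,64.5,NA,0.1,1.4,27.6,22.4,48.2,0.4,0.0,42,0.98,FALSE
32,75.5,141.5,110.0,41.5,58.0,NA,0.6,13.1,6.9,35.3,6.1,23.5,14.6,31,0.90,FALSE
33,88.5,166.0,100.0,48.0,66.0,NA,0.0,2.7,62.2,1.0,3.9,18.7,11.6,48,0.97,FALSE
34,88.0,161.5,103.0,47.5,69.5,NA,15.1,0.5,34.1,16.2,18.5,6.7,8.9,66,0.92,FALSE
35,69.5,142.0,95.5,39.0,58.5,NA,4.3,3.0,52.4,25.2,7.1,6.9,1.0,31,0.92,FALSE
36,87.5,159.0,104.5,42.5,66.5,NA,0.0,0.0,3.9,20.8,22.4,19.7,33.1,35,0.94,TRUE
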