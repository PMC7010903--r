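# Reference self S values (Gy per Bq s) to the nucleus for the nine
# polygonal-mesh models of imaged U2OS+SST2 cells, with cell and nucleus
# volumes (um^3). Sources: cytoplasm (Cy), Golgi (G), cell membrane (CS).
cell,v_cell_um3,v_nucleus_um3,s_cytoplasm,s_golgi,s_membrane
1,3603,1334,4.64e-05,6.96e-05,5.16e-05
2,3466,1374,6.67e-05,1.05e-04,6.39e-05
3,1877,721,7.05e-05,1.22e-04,7.79e-05
4,1853,722,7.27e-05,5.41e-05,7.66e-05
5,3932,1004,5.10e-05,8.57e-05,4.79e-05
6,4228,1096,5.30e-05,1.32e-04,4.60e-05
7,4149,1155,6.46e-05,1.05e-04,5.63e-05
8,3495,915,5.78e-05,8.12e-05,5.70e-05
9,5309,1231,4.27e-05,8.71e-05,4.20e-05
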