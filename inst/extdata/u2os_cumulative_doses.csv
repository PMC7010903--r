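# Reference cumulative absorbed doses to the nucleus (Gy) per added
# activity (MBq/ml) under four geometrical modeling assumptions: MIRD-style
# spheres, truncated cone with internalized source in cytoplasm (TC_Cy),
# polygonal meshes with internalized source in cytoplasm (PM_Cy) or
# Golgi (PM_G).
activity_MBq_per_ml,scenario,dose_Gy,dose_sd_Gy
0.1,sphere,0.42,0.05
0.1,TC_Cy,0.20,0.02
0.1,PM_Cy,0.14,0.04
0.1,PM_G,0.20,0.07
0.25,sphere,1.08,0.13
0.25,TC_Cy,0.52,0.06
0.25,PM_Cy,0.35,0.09
0.25,PM_G,0.51,0.18
0.5,sphere,2.77,0.30
0.5,TC_Cy,1.39,0.15
0.5,PM_Cy,0.92,0.25
0.5,PM_G,1.36,0.47
1,sphere,2.63,0.36
1,TC_Cy,1.36,0.18
1,PM_Cy,0.92,0.25
1,PM_G,1.33,0.47
2.5,sphere,5.64,0.96
2.5,TC_Cy,2.95,0.47
2.5,PM_Cy,2.04,0.60
2.5,PM_G,2.86,1.08
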