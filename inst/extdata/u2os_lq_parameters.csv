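# Reference linear-quadratic fit parameters for the clonogenic survival of
# U2OS+SST2 cells: 86-keV x-ray irradiation (LQ, beta > 0) and the Lu-177
# radiopharmaceutical exposure under four dosimetric modeling assumptions
# (linear regime, alpha/beta > 100 Gy, beta = 0).
exposure,alpha,alpha_sd,beta,beta_sd,r_squared
xray,0.27,0.08,0.23,0.06,0.99
sphere,0.19,0.20,0,,0.67
TC_Cy,0.32,0.38,0,,0.66
PM_Cy,0.47,0.19,0,,0.65
PM_G,0.33,0.13,0,,0.66
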