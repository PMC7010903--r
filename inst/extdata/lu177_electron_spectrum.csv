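# Lu-177 electron emission table (compiled approximation, synthetic fixture).
# Beta branches: endpoint energy and branch yield per decay; spectral shape
# is the allowed-shape Fermi approximation computed at load time.
# Discrete rows: dominant internal-conversion and Auger electron lines.
# Yields are electrons per decay. Swap in a user table for other compilations.
type,energy_keV,yield,density
beta,498.3,0.791,
beta,385.3,0.090,
beta,177.0,0.118,
discrete,5.8,0.067,
discrete,7.3,0.030,
discrete,47.6,0.0497,
discrete,101.7,0.0078,
discrete,105.3,0.0060,
discrete,110.7,0.0138,
discrete,143.1,0.0042,
discrete,164.6,0.0019,
discrete,175.5,0.0013,
discrete,206.8,0.0011,
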