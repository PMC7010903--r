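# Reference mean monolayer S values (Gy per Bq s): self + cross-dose to the
# nucleus of the polygonal-mesh cell models for the 4-h uptake (cells at 1
# diameter spacing) and the colony-forming follow-up days (clusters of
# increasing size). Medium column: whole-well medium source.
interval,membrane,cytoplasm,golgi,medium
uptake,6.17e-05,6.23e-05,9.75e-05,9.43e-12
day1,5.77e-05,5.84e-05,9.35e-05,9.43e-12
day2,6.07e-05,6.13e-05,9.65e-05,
day3,6.66e-05,6.70e-05,1.02e-04,
day4,7.30e-05,7.33e-05,1.08e-04,
day5,7.73e-05,7.76e-05,1.13e-04,
day6,8.01e-05,8.03e-05,1.15e-04,
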