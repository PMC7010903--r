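# Shared fixtures: computed once per test run.
spec_lu <- load_emission_spectrum()
mat_water <- material_water()
mat_lipid <- material_lipid()
cell_avg <- tc_cell()

# independent trapezoid (oracle helper, deliberately simple)
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

write_spectrum_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("type,energy_keV,yield,density", rows), path)
  path
}
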