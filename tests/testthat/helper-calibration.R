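# one calibration shared by all test files (calibrate_model caches internally,
# but keep an explicit handle for readability)
test_cal <- calibrate_model()

# the single-stimulation reference run used across files
test_single <- run_simulation(protocol("single"), test_cal)

# conserved volume-weighted totals along a trace (extracellular-equivalent mM)
total_k <- function(tr) tr$K_o + tr$K_n / 0.5 + tr$K_a / 0.5
total_na <- function(tr) tr$Na_o + tr$Na_n / 0.5 + tr$Na_a / 0.5
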