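# Shared fixtures: the default calibrated model, built once per test run.
# All stochastic tests draw through explicit seeds; 1 is the suite-wide
# default seed.
TEST_SEED <- 1

cal_default <- calibrate_baseline()

# independent quadrature for oral AUC checks
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
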