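# Shared fixtures: small deterministic specs used across test files.

# A spec whose cells all carry exactly `fu` FU (sigma 0, no zeros):
# makes painted signal analytically predictable.
const_spec <- function(fu, code = "I3",
                       len_range = c(6.3, 7.7)) {
  treatment_spec(code, "inorganic", 10, activity_median_FU = fu,
                 activity_sigma_log = 0, zero_fraction = 0,
                 cell_length_um_range = len_range)
}

# Relative error tolerant of exact zeros.
rel_err <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), .Machine$double.eps)
}
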