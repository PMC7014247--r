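# Shared fixture builders. Everything is generated in code; the standard
# calibration design is the 4 x 4 acesulfame K x NaCl factorial.

standard_design <- function() {
  make_design(c(0, 0.25, 0.5, 1), c(0, 10, 30, 50))
}

# a bare-mode forward model on a blank-free grid (the bare model is
# undefined at zero concentration)
bare_params <- function() {
  forward_params(a = -50.75, b = -47.6,
                 p = 3.8, h = 0.037, q = 0.04, i = 0.037,
                 offset_mode = "bare")
}

bare_design <- function() {
  make_design(c(0.1, 0.25, 0.5, 1), c(5, 10, 30, 50))
}

# noise-free calibration table from an arbitrary forward model
clean_table <- function(design, params) {
  resp <- forward_response(design$x_mM, design$y_mM, params)
  tibble::tibble(sample_id = design$sample_id,
                 x_mM = design$x_mM, y_mM = design$y_mM,
                 F_mV = resp$F_mV, G_mV = resp$G_mV)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
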