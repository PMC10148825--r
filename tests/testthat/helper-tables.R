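# Frozen expected values for the bundled RTK-inhibitor case study under
# paper-mode arithmetic (3-dp half-up rounding after normalization and after
# aggregation). Flow values were cross-checked against oracle_promethee()
# applied to the rounded intermediates.

alts9 <- paste0("In", 1:9)

# expected normalized matrix (3 dp)
expected_normalized <- matrix(c(
  0,     0.250, 0,
  0,     0.250, 0,
  1,     0,     0,
  1,     0.666, 1,
  0,     0,     0,
  1,     0.333, 1,
  0.499, 0,     0,
  1,     0.250, 0,
  1,     1,     0
), nrow = 9, byrow = TRUE, dimnames = list(alts9, c("GF1", "GF2", "GF3")))

# expected aggregated preference indices (3 dp), diagonal NA; rows = z, cols = y
expected_pi <- matrix(c(
  NA,    0,     0.088, 0,     0.088, 0,     0.088, 0,     0,
  0,     NA,    0.088, 0,     0.088, 0,     0.088, 0,     0,
  0.450, 0.450, NA,    0,     0.450, 0,     0.225, 0,     0,
  0.796, 0.796, 0.433, NA,    0.883, 0.117, 0.659, 0.346, 0.200,
  0,     0,     0,     0,     NA,    0,     0,     0,     0,
  0.679, 0.679, 0.317, 0,     0.767, NA,    0.542, 0.229, 0.200,
  0.225, 0.225, 0,     0,     0.225, 0,     NA,    0,     0,
  0.450, 0.450, 0.088, 0,     0.538, 0,     0.313, NA,    0,
  0.713, 0.713, 0.350, 0.117, 0.800, 0.233, 0.575, 0.263, NA
), nrow = 9, byrow = TRUE, dimnames = list(alts9, alts9))

# expected flows (paper mode, exact 6-dp values)
expected_phi_plus <- c(In1 = 0.033000, In2 = 0.033000, In3 = 0.196875,
                       In4 = 0.528750, In5 = 0.000000, In6 = 0.426625,
                       In7 = 0.084375, In8 = 0.229875, In9 = 0.470500)
expected_phi_minus <- c(In1 = 0.414125, In2 = 0.414125, In3 = 0.170500,
                        In4 = 0.014625, In5 = 0.479875, In6 = 0.043750,
                        In7 = 0.311250, In8 = 0.104750, In9 = 0.050000)
expected_phi_net <- expected_phi_plus - expected_phi_minus
expected_rank <- c(In1 = 7L, In2 = 7L, In3 = 5L, In4 = 1L, In5 = 9L,
                   In6 = 3L, In7 = 6L, In8 = 4L, In9 = 2L)
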