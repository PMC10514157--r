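# Parameter sets for the worked examples: the four discrete response
# scenarios, the beyond-perfect-mixing maximum, and three continuous
# scenarios. A fourth continuous example sometimes presented as unimodally
# beneficial is not used as a fixture: its competition strengths satisfy
# the beneficial-turning-detrimental condition.
fix_mono_ben    <- two_patch(3,    1.5,  2,    1.5)
fix_uni_ben     <- two_patch(3.2,  1.5,  3.85, 1.37)
fix_ben_detr    <- two_patch(3.4,  1.5,  8.4,  1.37)
fix_mono_detr   <- two_patch(2,    1.25, 1,    1.25)
fix_beyond_half <- two_patch(2.35, 1.7,  2.35, 1.75)

fix_c_mono_ben  <- two_patch(0.5, 2, 0.5, 1,   mode = "continuous")
fix_c_ben_detr  <- two_patch(1,   2, 0.5, 1.5, mode = "continuous")
fix_c_mono_detr <- two_patch(1.1, 2, 2,   1,   mode = "continuous")

discrete_fixtures <- list(
  monotonically_beneficial = fix_mono_ben,
  unimodally_beneficial = fix_uni_ben,
  beneficial_turning_detrimental = fix_ben_detr,
  monotonically_detrimental = fix_mono_detr)

# random admissible model, away from degenerate equalities
random_model <- function(mode = "discrete") {
  if (mode == "discrete")
    two_patch(runif(1, 1.1, 4), runif(1, 1.1, 4),
              runif(1, 0.5, 5), runif(1, 0.5, 5))
  else
    two_patch(runif(1, 0.2, 3), runif(1, 0.2, 3),
              runif(1, 0.5, 5), runif(1, 0.5, 5), mode = "continuous")
}
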