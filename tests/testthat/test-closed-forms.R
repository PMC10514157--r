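# raw (sign-carrying) value of the second-zero expression, evaluated
# directly from the parameters; independent of the package's guarded
# accessor, which reports only zeros inside the admissible range
raw_delta_tilde <- function(m) {
  with(m, K_A * K_B * (r_A - 1) * (r_B - 1) * (r_A - r_B) /
         ((K_A * (r_B - 1) + K_B * (r_A - 1)) *
            (K_A * r_A * (r_B - 1) - K_B * r_B * (r_A - 1))))
}

test_that("the closed-form second zero matches its numeric bisection", {
  expect_equal(delta_tilde(fix_ben_detr), 26.23824 / 69.9978,
               tolerance = 1e-6)
  expect_equal(delta_tilde(fix_ben_detr), numeric_zero_H(fix_ben_detr),
               tolerance = 1e-6)
  # K_B/K_A equal to the growth-surplus ratio puts the zero at 0.5 exactly
  expect_equal(delta_tilde(two_patch(3, 1.5, 2, 0.5)), 0.5)
  # equal growth rates: zero dispersal is the only zero
  expect_null(delta_tilde(two_patch(2, 2, 3, 1)))
  expect_error(delta_tilde(two_patch(2, 1.5, 1, 1)), "equal carrying")
  # random draws in the sign-change region agree with the bisection root
  ps <- generate_scenario_params(
    8, "discrete", target_label = "beneficial_turning_detrimental",
    seed = 31)
  for (m in ps) {
    mcan <- canonicalize(m)$model
    dt <- delta_tilde(mcan)
    expect_false(is.null(dt))
    expect_equal(numeric_zero_H(mcan), dt, tolerance = 1e-6)
  }
})

test_that("sign of the raw second-zero expression obeys the ratio bands", {
  set.seed(32)
  for (i in 1:50) {
    m <- canonicalize(random_model())$model
    if (m$r_A == m$r_B || m$K_A == m$K_B) next
    ratio <- m$K_B / m$K_A
    lo <- sqrt(m$r_A) * (m$r_B - 1) / (sqrt(m$r_B) * (m$r_A - 1))
    hi <- m$r_A * (m$r_B - 1) / (m$r_B * (m$r_A - 1))
    if (abs(ratio - lo) < 1e-9 || abs(ratio - hi) < 1e-9) next
    rdt <- raw_delta_tilde(m)
    expect_identical(rdt < 0, ratio > hi)
    expect_identical(rdt >= 1, ratio >= lo && ratio < hi)
  }
})

test_that("quadratic coefficients have the expected signs and roots", {
  m <- fix_uni_ben
  q <- quadratic_and_nbar(m)
  expect_gt(q$a, 0)
  expect_lt(q$c, 0)  # opposite signs: one positive and one negative root
  expect_gt(q$Nbar_B, 0)
  expect_equal(q$a * q$Nbar_B^2 + q$b * q$Nbar_B + q$c, 0,
               tolerance = 1e-9)
  # equal growth rates collapse the largest root onto K_B
  sym_r <- two_patch(2.4, 2.4, 3, 1.2)
  expect_equal(quadratic_and_nbar(sym_r)$Nbar_B, 1.2, tolerance = 1e-12)
  # the maximum subpopulation sizes reproduce the numeric maximum of H
  peak <- numeric_argmax_H(m)
  expect_equal(q$Nbar_A + q$Nbar_B, peak$H + m$K_A + m$K_B,
               tolerance = 1e-8)
  expect_error(quadratic_and_nbar(two_patch(1.5, 3, 1, 1)), "canonical")
})

test_that("closed-form argmax agrees with golden-section search", {
  dm_b <- delta_max(fix_uni_ben)
  expect_true(dm_b$interior)
  expect_gt(dm_b$delta_max, 0)
  expect_lt(dm_b$delta_max, 0.5)
  expect_equal(dm_b$delta_max, numeric_argmax_H(fix_uni_ben)$delta,
               tolerance = 1e-4)
  # the maximum can sit beyond perfect mixing
  dm_5 <- delta_max(fix_beyond_half)
  expect_gt(dm_5$delta_max, 0.5)
  expect_lt(dm_5$delta_max, 1)
  expect_equal(dm_5$delta_max, numeric_argmax_H(fix_beyond_half)$delta,
               tolerance = 1e-4)
  # equal growth rates: the response only decreases
  expect_equal(delta_max(two_patch(2, 2, 3, 1))$delta_max, 0)
  # property: wherever the closed form reports an interior maximum the
  # numeric search lands on it
  set.seed(33)
  n_checked <- 0
  while (n_checked < 10) {
    m <- canonicalize(random_model())$model
    if (m$K_A == m$K_B) next
    dm <- delta_max(m)
    if (!dm$interior || dm$delta_max < 0.01 || dm$delta_max > 0.99) next
    expect_equal(numeric_argmax_H(m)$delta, dm$delta_max, tolerance = 1e-4)
    n_checked <- n_checked + 1
  }
})

test_that("the right derivative of H at zero matches finite differences", {
  expect_equal(h_prime_zero(fix_mono_ben), 0.75)
  expect_equal(h_prime_zero(two_patch(2, 1.5, 3, 3)), 0)
  expect_equal(h_prime_zero(two_patch(2, 2, 3, 1)), 0)
  h <- 1e-6
  set.seed(34)
  for (i in 1:10) {
    m <- random_model()
    fd <- H_dispersal(m, h) / h
    an <- h_prime_zero(m)
    expect_equal(fd, an, tolerance = 1e-4)
  }
  # continuous counterpart
  for (i in 1:10) {
    mc <- random_model("continuous")
    can <- canonicalize(mc)$model
    fd <- H_dispersal(can, h) / h
    expect_equal(fd, continuous_limits(can)$H_prime_zero, tolerance = 1e-4)
  }
})

test_that("maximum-total closed forms cover the three regimes", {
  # interior maximum
  mx_b <- max_population_summary(fix_uni_ben)
  expect_equal(mx_b$argmax_delta, delta_max(fix_uni_ben)$delta_max)
  q <- quadratic_and_nbar(fix_uni_ben)
  expect_equal(mx_b$max_total, q$Nbar_A + q$Nbar_B)
  # faster growth in the smaller patch: best to stay disconnected
  mx_d <- max_population_summary(two_patch(2, 1.25, 1, 1.25))
  expect_equal(mx_d$max_total, 2.25)
  expect_equal(mx_d$argmax_delta, 0)
  # monotone beneficial: best at complete replacement, with the
  # replacement-equilibrium subpopulation values
  mx_a <- max_population_summary(fix_mono_ben)
  expect_equal(mx_a$argmax_delta, 1)
  expect_equal(mx_a$N_A_1, 1.75)
  expect_equal(mx_a$N_B_1, 21 / 11)
  expect_equal(mx_a$max_total, 1.75 + 21 / 11)
  # the displayed replacement total equals the sum of the two closed forms
  m <- fix_mono_ben
  disp <- with(m, K_A * K_B *
    (K_A * (r_A + 1) * (r_B - 1) + K_B * (r_B + 1) * (r_A - 1)) *
    (r_A * r_B - 1) /
    ((K_A * r_A * (r_B - 1) + K_B * (r_A - 1)) *
       (K_A * (r_B - 1) + K_B * r_B * (r_A - 1))))
  expect_equal(mx_a$max_total, disp)
})

test_that("numeric response curves never exceed the closed-form maximum", {
  for (m in list(fix_mono_ben, fix_uni_ben, fix_ben_detr, fix_beyond_half)) {
    mx <- max_population_summary(m)
    rc <- response_curve(m, points = 201)
    tot <- rc$N_A + rc$N_B
    expect_true(all(tot <= mx$max_total + 1e-6))
    expect_lt(mx$max_total - max(tot), 1e-4)
  }
})

test_that("continuous limit expressions match their printed forms", {
  lim <- continuous_limits(fix_c_ben_detr)
  expect_equal(lim$H_inf, -0.2)           # (K_B-K_A)(r_B K_A - r_A K_B)/(...)
  expect_equal(lim$H_prime_zero, 0.5)     # (1.5-0.5)(2-1)/(1*2)
  lim_eq <- continuous_limits(two_patch(1, 2, 1.3, 1.3, mode = "continuous"))
  expect_equal(lim_eq$H_inf, 0)
  expect_equal(lim_eq$H_prime_zero, 0)
  expect_equal(lim_eq$Hprime_inf_criterion, 0)
  expect_error(continuous_limits(fix_c_mono_detr), "canonical")
})

test_that("threshold constants exceed one in both time modes", {
  expect_equal(kappa_discrete(two_patch(3, 1.5, 2, 1.5)),
               (3 + sqrt(4.5) - 2) / (1.5 + sqrt(4.5) - 2))
  expect_equal(kappa_discrete(two_patch(3.2, 1.5, 1, 2)), 2.0054,
               tolerance = 1e-4)
  expect_equal(kappa_continuous(fix_c_mono_ben), 6.5 / 3.5)
  # orientation invariance and the >1 guarantee
  set.seed(36)
  for (i in 1:30) {
    m <- random_model()
    if (abs(m$r_A - m$r_B) < 1e-3) next
    expect_gt(kappa_discrete(m), 1)
    expect_equal(kappa_discrete(m), kappa_discrete(swap_patches(m)))
    mc <- random_model("continuous")
    if (abs(mc$r_A - mc$r_B) < 1e-3) next
    expect_gt(kappa_continuous(mc), 1)
    expect_equal(kappa_continuous(mc), kappa_continuous(swap_patches(mc)))
  }
  # near-equal growth rates drive the discrete constant to 1
  expect_equal(kappa_discrete(two_patch(2.0001, 2, 1, 2)), 1,
               tolerance = 1e-3)
  expect_error(kappa_discrete(two_patch(2, 2, 1, 2)), "equal growth")
})

test_that("restricted-range band places the unimodal fixture correctly", {
  # competition-ratio bands: the unimodal fixture's capacity ratio lies in
  # [rho, kappa * rho) with rho the growth-surplus ratio
  m <- fix_uni_ben
  rho <- (m$r_B - 1) / (m$r_A - 1)
  k <- kappa_discrete(m)
  ratio <- m$K_B / m$K_A
  expect_gte(ratio, rho)
  expect_lt(ratio, k * rho)
  expect_equal(rho, 0.22727, tolerance = 1e-4)
  expect_equal(k * rho, 0.45578, tolerance = 1e-4)
})

test_that("the model summary collects the analytic quantities", {
  sm <- summary(fix_ben_detr)
  expect_s3_class(sm, "summary.two_patch")
  expect_equal(sm$delta_tilde, delta_tilde(fix_ben_detr))
  expect_equal(sm$classification$label, "beneficial_turning_detrimental")
  expect_output(print(sm), "delta_tilde")
  js <- jsonlite::fromJSON(summary_to_json(sm))
  expect_equal(js$delta_tilde, delta_tilde(fix_ben_detr), tolerance = 1e-12)
  expect_identical(js$label, "beneficial_turning_detrimental")
  smc <- summary(fix_c_mono_ben)
  expect_equal(smc$kappa_c, 6.5 / 3.5)
  expect_output(print(smc), "kappa_c")
})
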