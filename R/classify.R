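scenario_labels <- c("monotonically_beneficial", "unimodally_beneficial",
                     "beneficial_turning_detrimental",
                     "monotonically_detrimental", "neutral_equal_K")

new_scenario_label <- function(label, swapped = FALSE, boundary = FALSE) {
  label <- match.arg(label, scenario_labels)
  structure(list(label = label, swapped = swapped, boundary = boundary),
            class = "scenario_label")
}

#' @export
print.scenario_label <- function(x, ...) {
  cat("Response scenario: ", x$label, "\n", sep = "")
  if (x$swapped) cat("  (patches relabeled to canonical order)\n")
  if (x$boundary) cat("  (within tolerance of a region boundary)\n")
  invisible(x)
}

# relative comparison helpers: classifications within rel_tol of a
# threshold are flagged so property tests can exclude boundary draws
rel_close <- function(a, b, rel_tol = 1e-9) {
  abs(a - b) <= rel_tol * max(abs(a), abs(b), 1)
}

#' Canonical orientation of a two-patch model
#'
#' The closed forms and classifiers assume a fixed orientation: in
#' discrete mode patch A is the faster-growing patch (`r_B <= r_A`), in
#' continuous mode patch A is the smaller patch (`K_A <= K_B`). Patch
#' relabeling is lossless because the model family is symmetric under it.
#'
#' @param model a [two_patch()] model.
#' @return List with elements `model` (possibly swapped) and `swapped`
#'   (logical).
#' @examples
#' canonicalize(two_patch(1.1, 2, 2, 1, mode = "continuous"))$swapped  # TRUE
#' @export
canonicalize <- function(model) {
  assert_two_patch(model)
  swap <- if (model$mode == "discrete") model$r_B > model$r_A
          else model$K_B < model$K_A
  list(model = if (swap) swap_patches(model) else model, swapped = swap)
}

#' Classify the dispersal-response scenario of a two-patch model
#'
#' Determines, from the parameters alone, the qualitative shape of the
#' dispersal-response function H: one of `monotonically_beneficial`,
#' `unimodally_beneficial`, `beneficial_turning_detrimental`,
#' `monotonically_detrimental`, or `neutral_equal_K` (equal carrying
#' capacities leave the total unchanged at every dispersal rate). The
#' degenerate equal-`r` case is folded into the monotonically detrimental
#' scenario, matching its qualitative shape.
#'
#' For a discrete model, `range = "full"` classifies H on the whole unit
#' interval and `range = "half"` on `[0, 0.5]` (isolation to perfect
#' mixing), which is the range comparable to the continuous model. The
#' restricted classifier works by comparing the closed-form zero and
#' argmax of H against 0.5. Continuous models ignore `range`.
#'
#' @param model a [two_patch()] model.
#' @param range `"full"` or `"half"` (discrete mode only).
#' @param rel_tol relative tolerance for boundary detection; inputs within
#'   tolerance of a defining inequality are classified by that inequality's
#'   non-strict side and flagged with `boundary = TRUE`.
#' @return An object of class `"scenario_label"`: list with elements
#'   `label`, `swapped`, `boundary`.
#' @examples
#' classify(two_patch(3, 1.5, 2, 1.5))$label      # monotonically_beneficial
#' classify(two_patch(2, 1.25, 1, 1.25))$label    # monotonically_detrimental
#' classify(two_patch(0.5, 2, 0.5, 1, "continuous"))$label
#' @export
classify <- function(model, range = c("full", "half"), rel_tol = 1e-9) {
  assert_two_patch(model)
  range <- match.arg(range)
  if (model$mode == "continuous") {
    classify_continuous(model, rel_tol = rel_tol)
  } else if (range == "full") {
    classify_discrete_full(model, rel_tol = rel_tol)
  } else {
    classify_discrete_restricted(model, rel_tol = rel_tol)
  }
}

classify_discrete_full <- function(model, rel_tol = 1e-9) {
  assert_two_patch(model, "discrete")
  can <- canonicalize(model)
  m <- can$model
  rA <- m$r_A; rB <- m$r_B; KA <- m$K_A; KB <- m$K_B
  boundary <- FALSE
  if (KA == KB)
    return(new_scenario_label("neutral_equal_K", can$swapped,
                              rel_close(rA, rB, rel_tol)))
  if (rel_close(rA, rB, rel_tol)) boundary <- TRUE
  if (rA == rB)
    return(new_scenario_label("monotonically_detrimental", can$swapped,
                              boundary))
  ratio <- KB / KA
  if (rel_close(ratio, 1, rel_tol)) boundary <- TRUE
  if (ratio > 1)
    return(new_scenario_label("monotonically_detrimental", can$swapped,
                              boundary))
  thr <- sqrt(rA) * (rB - 1) / (sqrt(rB) * (rA - 1))
  if (rel_close(ratio, thr, rel_tol)) boundary <- TRUE
  if (ratio < thr)
    return(new_scenario_label("beneficial_turning_detrimental", can$swapped,
                              boundary))
  dm <- delta_max(m)
  if (rel_close(dm$delta_max, 0, rel_tol) || rel_close(dm$delta_max, 1, rel_tol))
    boundary <- TRUE
  label <- if (dm$interior) "unimodally_beneficial" else
    "monotonically_beneficial"
  new_scenario_label(label, can$swapped, boundary)
}

# restricted range [0, 0.5]: authoritative route compares the closed-form
# zero and argmax of H against 0.5; the threshold-inequality route of the
# restricted statement is kept as a cross-check in the test suite
classify_discrete_restricted <- function(model, rel_tol = 1e-9) {
  assert_two_patch(model, "discrete")
  can <- canonicalize(model)
  m <- can$model
  boundary <- FALSE
  if (m$K_A == m$K_B)
    return(new_scenario_label("neutral_equal_K", can$swapped,
                              rel_close(m$r_A, m$r_B, rel_tol)))
  if (rel_close(m$r_A, m$r_B, rel_tol)) boundary <- TRUE
  if (m$r_A == m$r_B)
    return(new_scenario_label("monotonically_detrimental", can$swapped,
                              boundary))
  ratio <- m$K_B / m$K_A
  if (rel_close(ratio, 1, rel_tol)) boundary <- TRUE
  if (ratio > 1)
    return(new_scenario_label("monotonically_detrimental", can$swapped,
                              boundary))
  dt <- delta_tilde(m)
  if (!is.null(dt) && rel_close(dt, 0.5, rel_tol)) boundary <- TRUE
  if (!is.null(dt) && dt < 0.5)
    return(new_scenario_label("beneficial_turning_detrimental", can$swapped,
                              boundary))
  dm <- delta_max(m)
  if (rel_close(dm$delta_max, 0.5, rel_tol) ||
      rel_close(dm$delta_max, 0, rel_tol)) boundary <- TRUE
  label <- if (dm$delta_max > 0 && dm$delta_max < 0.5)
    "unimodally_beneficial" else "monotonically_beneficial"
  new_scenario_label(label, can$swapped, boundary)
}

classify_continuous <- function(model, rel_tol = 1e-9) {
  assert_two_patch(model, "continuous")
  can <- canonicalize(model)
  m <- can$model
  rA <- m$r_A; rB <- m$r_B; KA <- m$K_A; KB <- m$K_B
  boundary <- FALSE
  if (KA == KB)
    return(new_scenario_label("neutral_equal_K", can$swapped,
                              rel_close(rA, rB, rel_tol)))
  if (rel_close(rA, rB, rel_tol)) boundary <- TRUE
  if (rA >= rB)
    return(new_scenario_label("monotonically_detrimental", can$swapped,
                              boundary))
  xiA <- rA / KA; xiB <- rB / KB
  kc <- kappa_continuous(m)
  if (rel_close(xiB, xiA, rel_tol) || rel_close(xiB, kc * xiA, rel_tol))
    boundary <- TRUE
  if (xiB >= kc * xiA)
    return(new_scenario_label("monotonically_beneficial", can$swapped,
                              boundary))
  if (xiB >= xiA)
    return(new_scenario_label("unimodally_beneficial", can$swapped, boundary))
  new_scenario_label("beneficial_turning_detrimental", can$swapped, boundary)
}

#' Empirical scenario classification from a numeric response curve
#'
#' Labels the response scenario from the numeric H values alone, without
#' touching the analytic conditions. Intended as an independent oracle for
#' validating the parameter-condition classifiers and for parameter
#' sweeps. Near the equal-growth-rate boundary the sign change of H can sit
#' arbitrarily close to zero dispersal, so curves evaluated on log-spaced
#' grids (the continuous-mode default) resolve the shape far more reliably
#' than uniform grids.
#'
#' @param curve a [response_curve()] object with at least 21 grid points
#'   (at least 101 recommended for reliable shape detection).
#' @param tol absolute tolerance below which H values count as zero.
#' @return An object of class `"scenario_label"` (with `swapped = FALSE`;
#'   the curve carries no orientation).
#' @examples
#' m <- two_patch(2, 1.25, 1, 1.25)
#' classify_empirical(response_curve(m, points = 101))$label
#' @export
classify_empirical <- function(curve, tol = 1e-8) {
  stopifnot(inherits(curve, "response_curve"))
  if (nrow(curve) < 21L)
    stop("curve too coarse for empirical classification (need >= 21 points)",
         call. = FALSE)
  H <- curve$H
  if (all(abs(H) <= tol))
    return(new_scenario_label("neutral_equal_K"))
  any_pos <- any(H > tol)
  any_neg <- any(H < -tol)
  if (any_pos && any_neg)
    return(new_scenario_label("beneficial_turning_detrimental"))
  if (any_neg)
    return(new_scenario_label("monotonically_detrimental"))
  # beneficial: unimodal iff the curve comes back down from its maximum
  if (max(H) > H[length(H)] + tol)
    return(new_scenario_label("unimodally_beneficial"))
  new_scenario_label("monotonically_beneficial")
}
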