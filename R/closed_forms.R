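#' Closed-form second zero of H (discrete mode)
#'
#' The dispersal-response function H of the discrete model vanishes at
#' \eqn{\delta = 0} and can have at most one further zero,
#' \deqn{\tilde\delta = \frac{K_A K_B (r_A-1)(r_B-1)(r_A-r_B)}
#'   {(K_A(r_B-1)+K_B(r_A-1))\,(K_A r_A(r_B-1)-K_B r_B(r_A-1))}.}
#' The value is only an actual zero of H when it falls in `(0, 1]`;
#' otherwise zero dispersal is the unique zero and `NULL` is returned.
#'
#' @param model a [two_patch()] model in discrete mode with
#'   `K_A != K_B` (with equal carrying capacities H is identically zero
#'   and the question is void).
#' @return The dispersal rate of the second zero, or `NULL` when H has no
#'   zero in `(0, 1]` (equal growth rates, vanishing denominator factor, or
#'   a value outside the unit interval).
#' @examples
#' delta_tilde(two_patch(3.4, 1.5, 8.4, 1.37))  # about 0.3748
#' delta_tilde(two_patch(2, 2, 1, 3))           # NULL: equal growth rates
#' @export
delta_tilde <- function(model) {
  assert_two_patch(model, "discrete")
  if (model$K_A == model$K_B)
    stop("delta_tilde is undefined for equal carrying capacities",
         call. = FALSE)
  rA <- model$r_A; rB <- model$r_B; KA <- model$K_A; KB <- model$K_B
  if (rA == rB) return(NULL)
  den2 <- KA * rA * (rB - 1) - KB * rB * (rA - 1)
  if (den2 == 0) return(NULL)
  val <- KA * KB * (rA - 1) * (rB - 1) * (rA - rB) /
    ((KA * (rB - 1) + KB * (rA - 1)) * den2)
  if (val <= 0 || val > 1) return(NULL)
  val
}

#' Quadratic coefficients and maximum subpopulation sizes (discrete mode)
#'
#' The maximum asymptotic subpopulation size of patch B,
#' \eqn{\bar N_B}, is the largest root of \eqn{a y^2 + b y + c = 0} with
#' coefficients built from the four demographic parameters; \eqn{\bar N_A}
#' follows from it in closed form. Requires the canonical orientation
#' \eqn{1 < r_B \le r_A}.
#'
#' @param model a [two_patch()] model in discrete mode with
#'   `r_B <= r_A`.
#' @return List with elements `a`, `b`, `c`, `Nbar_B`, `Nbar_A`.
#' @examples
#' quadratic_and_nbar(two_patch(3.2, 1.5, 3.85, 1.37))
#' @export
quadratic_and_nbar <- function(model) {
  assert_two_patch(model, "discrete")
  rA <- model$r_A; rB <- model$r_B; KA <- model$K_A; KB <- model$K_B
  if (rB > rA)
    stop("quadratic_and_nbar requires the canonical orientation r_B <= r_A",
         call. = FALSE)
  sA <- sqrt(rA); sB <- sqrt(rB)
  a <- (rB - 1) * (KA * sA * (rB - 1) + KB * sB * (rA - 1))
  b <- KB * (rB - 1) * (2 * KA * sA - (KA - KB + (KA + KB) * rA) * sB)
  c <- -KA * KB^2 * (sA - sB) * (sA * sB - 1)
  disc <- b^2 - 4 * a * c
  if (disc < -1e-12 * max(1, b^2))
    stop("negative discriminant: parameters outside the admissible regime",
         call. = FALSE)
  disc <- max(disc, 0)
  Nbar_B <- (-b + sqrt(disc)) / (2 * a)
  Nbar_A <- KA * (KB * (sA - sB) + sA * (rB - 1) * Nbar_B) /
    (KB * sB * (rA - 1))
  list(a = a, b = b, c = c, Nbar_B = Nbar_B, Nbar_A = Nbar_A)
}

#' Closed-form argmax of H (discrete mode)
#'
#' The dispersal rate at which H peaks,
#' \deqn{\delta_{max} = \frac{\bar N_B - f_B(\bar N_B)}
#'   {f_A(\bar N_A) - f_B(\bar N_B)},}
#' built from the maximum subpopulation sizes of [quadratic_and_nbar()].
#' H is strictly monotone on the unit interval when the value falls
#' outside `(0, 1)`, and increasing-then-decreasing with the maximum at
#' `delta_max` when inside.
#'
#' @param model a [two_patch()] model in discrete mode with
#'   `K_A != K_B` and `r_B <= r_A`.
#' @return List with elements `delta_max` (numeric) and `interior`
#'   (logical: whether the value lies in the open unit interval).
#' @examples
#' delta_max(two_patch(3.2, 1.5, 3.85, 1.37))$interior  # TRUE
#' @export
delta_max <- function(model) {
  assert_two_patch(model, "discrete")
  if (model$K_A == model$K_B)
    stop("delta_max is undefined for equal carrying capacities", call. = FALSE)
  if (model$r_A == model$r_B)
    return(list(delta_max = 0, interior = FALSE))
  nb <- quadratic_and_nbar(model)
  fA <- beverton_holt(nb$Nbar_A, model$r_A, model$K_A)
  fB <- beverton_holt(nb$Nbar_B, model$r_B, model$K_B)
  den <- fA - fB
  if (abs(den) < 1e-14 * max(1, abs(fA), abs(fB)))
    stop("degenerate denominator in delta_max: parameters violate the ",
         "assumed regime", call. = FALSE)
  val <- (nb$Nbar_B - fB) / den
  list(delta_max = val, interior = (val > 0 && val < 1))
}

#' Right derivative of H at zero dispersal (discrete mode)
#'
#' \deqn{H'(0^+) = \frac{(r_A - r_B)(K_A - K_B)}{(r_A - 1)(r_B - 1)}.}
#' Positive exactly when the patch with the larger carrying capacity also
#' has the larger growth rate, i.e. when a little dispersal is beneficial.
#'
#' @param model a [two_patch()] model in discrete mode.
#' @return The one-sided derivative (individuals per unit dispersal rate).
#' @examples
#' h_prime_zero(two_patch(3, 1.5, 2, 1.5))  # 0.75
#' @export
h_prime_zero <- function(model) {
  assert_two_patch(model, "discrete")
  (model$r_A - model$r_B) * (model$K_A - model$K_B) /
    ((model$r_A - 1) * (model$r_B - 1))
}

#' Equilibrium at complete replacement (discrete mode)
#'
#' At `delta = 1` the two patches swap their post-growth outputs each time
#' step and the fixed point has the closed form
#' \deqn{N_A(1) = \frac{K_A K_B (r_A r_B - 1)}{K_A r_A (r_B-1) + K_B (r_A-1)},
#'   \quad
#'   N_B(1) = \frac{K_A K_B (r_A r_B - 1)}{K_A (r_B-1) + K_B r_B (r_A-1)}.}
#'
#' @param model a [two_patch()] model in discrete mode.
#' @return Named numeric vector `c(N_A =, N_B =)`.
#' @examples
#' equilibrium_delta_one(two_patch(3, 1.5, 2, 1.5))  # c(1.75, 21/11)
#' @export
equilibrium_delta_one <- function(model) {
  assert_two_patch(model, "discrete")
  rA <- model$r_A; rB <- model$r_B; KA <- model$K_A; KB <- model$K_B
  num <- KA * KB * (rA * rB - 1)
  c(N_A = num / (KA * rA * (rB - 1) + KB * (rA - 1)),
    N_B = num / (KA * (rB - 1) + KB * rB * (rA - 1)))
}

#' Maximum asymptotic total population size (discrete mode)
#'
#' Closed-form maximum of the asymptotic total population size over
#' `delta` in `[0, 1]` and the dispersal rate at which it is attained:
#' an interior `delta_max` gives \eqn{\bar N_A + \bar N_B}; otherwise the
#' maximum sits at an endpoint — at `delta = 0` (total `K_A + K_B`) when
#' `r_A = r_B` or `K_A < K_B`, and at `delta = 1` (complete replacement,
#' with the [equilibrium_delta_one()] subpopulation values) when
#' `r_A > r_B` and `K_A > K_B`.
#'
#' @param model a [two_patch()] model in discrete mode with
#'   `r_B <= r_A` and `K_A != K_B`.
#' @return List with `max_total`, `argmax_delta`, and (when the maximum is
#'   at `delta = 1`) `N_A_1`, `N_B_1`.
#' @examples
#' max_population_summary(two_patch(3, 1.5, 2, 1.5))  # attained at delta = 1
#' @export
max_population_summary <- function(model) {
  assert_two_patch(model, "discrete")
  if (model$r_B > model$r_A)
    stop("max_population_summary requires the canonical orientation ",
         "r_B <= r_A", call. = FALSE)
  if (model$K_A == model$K_B)
    stop("max_population_summary requires K_A != K_B (with equal capacities ",
         "the total is K_A + K_B at every dispersal rate)", call. = FALSE)
  dm <- delta_max(model)
  if (dm$interior) {
    nb <- quadratic_and_nbar(model)
    return(list(max_total = nb$Nbar_A + nb$Nbar_B,
                argmax_delta = dm$delta_max))
  }
  if (model$r_A == model$r_B || model$K_A < model$K_B)
    return(list(max_total = model$K_A + model$K_B, argmax_delta = 0))
  eq1 <- equilibrium_delta_one(model)
  list(max_total = unname(eq1[1L] + eq1[2L]), argmax_delta = 1,
       N_A_1 = unname(eq1[1L]), N_B_1 = unname(eq1[2L]))
}

#' Limit quantities of the continuous response function
#'
#' The closed-form values characterising \eqn{H_c} at the two ends of the
#' dispersal range, for the canonical orientation \eqn{K_A < K_B}:
#' \deqn{H_c(\infty) = (K_B - K_A)\frac{r_B K_A - r_A K_B}{r_B K_A + r_A K_B},}
#' \deqn{H_c'(0^+) = (K_B - K_A)\frac{r_B - r_A}{r_A r_B},}
#' the large-dispersal slope criterion
#' \deqn{\mathbb H_c'(\infty) = \tfrac12 (K_B - K_A)(r_B - r_A)
#'   - 2 r_A r_B \frac{(K_B - K_A)^2}{r_B K_A + r_A K_B},}
#' and the threshold constant
#' \eqn{\kappa_c = (r_A + 3 r_B)/(r_B + 3 r_A)}.
#'
#' @param model a [two_patch()] model in continuous mode with
#'   `K_A <= K_B` (canonicalize first when needed, see [canonicalize()]).
#' @return List with elements `H_inf`, `H_prime_zero`,
#'   `Hprime_inf_criterion`, `kappa_c`.
#' @examples
#' continuous_limits(two_patch(1, 2, 0.5, 1.5, mode = "continuous"))$H_inf
#' @export
continuous_limits <- function(model) {
  assert_two_patch(model, "continuous")
  rA <- model$r_A; rB <- model$r_B; KA <- model$K_A; KB <- model$K_B
  if (KA > KB)
    stop("continuous_limits requires the canonical orientation K_A <= K_B; ",
         "apply canonicalize() first", call. = FALSE)
  list(
    H_inf = (KB - KA) * (rB * KA - rA * KB) / (rB * KA + rA * KB),
    H_prime_zero = (KB - KA) * (rB - rA) / (rA * rB),
    Hprime_inf_criterion = 0.5 * (KB - KA) * (rB - rA) -
      2 * rA * rB * (KB - KA)^2 / (rB * KA + rA * KB),
    kappa_c = kappa_continuous(model))
}

#' Threshold constants separating monotone from unimodal benefit
#'
#' Within the beneficial regime (larger patch grows faster) the response is
#' monotonically increasing when the intraspecific competition in the
#' larger patch exceeds that of the smaller patch by at least a factor
#' kappa, and unimodal otherwise. The discrete constant is
#' \deqn{\kappa_d = \frac{r_{fast} + \sqrt{r_A r_B} - 2}
#'   {r_{slow} + \sqrt{r_A r_B} - 2},}
#' oriented with the larger growth rate in the numerator so that
#' \eqn{\kappa_d > 1}; the continuous constant is
#' \eqn{\kappa_c = (r_A + 3 r_B)/(r_B + 3 r_A)} (in canonical order
#' \eqn{r_A < r_B}), likewise always above 1.
#'
#' @param model a [two_patch()] model of the matching mode. The discrete
#'   constant requires `r_A != r_B`.
#' @return The threshold constant, a number strictly greater than 1.
#' @examples
#' kappa_discrete(two_patch(3, 1.5, 2, 1.5))                      # 1.9252
#' kappa_continuous(two_patch(0.5, 2, 0.5, 1, "continuous"))      # 13/7
#' @export
kappa_discrete <- function(model) {
  assert_two_patch(model, "discrete")
  if (model$r_A == model$r_B)
    stop("kappa_discrete is undefined for equal growth rates", call. = FALSE)
  s <- sqrt(model$r_A * model$r_B)
  r_fast <- max(model$r_A, model$r_B)
  r_slow <- min(model$r_A, model$r_B)
  (r_fast + s - 2) / (r_slow + s - 2)
}

#' @rdname kappa_discrete
#' @export
kappa_continuous <- function(model) {
  assert_two_patch(model, "continuous")
  rA <- min(model$r_A, model$r_B)
  rB <- max(model$r_A, model$r_B)
  (rA + 3 * rB) / (rB + 3 * rA)
}

#' Closed-form summary of a two-patch model
#'
#' Collects every analytic quantity the model admits in its time mode:
#' zeros and argmax of the response function, its derivative at zero
#' dispersal, the maximum attainable total, the threshold constant, and
#' (continuous mode) the infinite-dispersal limits. The model is first
#' canonicalized to the orientation the formulas assume.
#'
#' @param object a [two_patch()] model.
#' @param ... unused.
#' @return An object of class `"summary.two_patch"`: a list with the
#'   canonical model, the swap flag, the scenario classification and the
#'   closed-form quantities (`NULL` where undefined).
#' @examples
#' summary(two_patch(3.4, 1.5, 8.4, 1.37))
#' @export
summary.two_patch <- function(object, ...) {
  can <- canonicalize(object)
  m <- can$model
  cls <- classify(object)
  out <- list(model = m, swapped = can$swapped, mode = m$mode,
              classification = cls)
  equal_K <- m$K_A == m$K_B
  if (m$mode == "discrete") {
    out$H_prime_zero <- h_prime_zero(m)
    out$kappa <- if (m$r_A != m$r_B) kappa_discrete(m) else NULL
    if (!equal_K) {
      out$delta_tilde <- delta_tilde(m)
      nb <- quadratic_and_nbar(m)
      out$Nbar_A <- nb$Nbar_A
      out$Nbar_B <- nb$Nbar_B
      dm <- delta_max(m)
      out$delta_max <- dm$delta_max
      out$delta_max_interior <- dm$interior
      mx <- max_population_summary(m)
      out$max_total <- mx$max_total
      out$argmax_delta <- mx$argmax_delta
    } else {
      out$max_total <- m$K_A + m$K_B
      out$argmax_delta <- 0
    }
  } else {
    lim <- continuous_limits(m)
    out$H_inf <- lim$H_inf
    out$H_prime_zero <- lim$H_prime_zero
    out$Hprime_inf_criterion <- lim$Hprime_inf_criterion
    out$kappa_c <- lim$kappa_c
  }
  class(out) <- "summary.two_patch"
  out
}

#' @export
print.summary.two_patch <- function(x, digits = 6, ...) {
  fmt <- function(v) if (is.null(v)) "none" else format(v, digits = digits)
  cat("Closed-form summary (", x$mode, " mode",
      if (x$swapped) ", patches relabeled to canonical order", ")\n",
      sep = "")
  print(x$model)
  cat("  scenario: ", x$classification$label,
      if (x$classification$boundary) " (near a region boundary)", "\n",
      sep = "")
  cat("  H'(0+):   ", fmt(x$H_prime_zero), "\n", sep = "")
  if (x$mode == "discrete") {
    cat("  delta_tilde (second zero of H): ", fmt(x$delta_tilde), "\n",
        sep = "")
    if (!is.null(x$delta_max))
      cat("  delta_max: ", fmt(x$delta_max),
          if (isTRUE(x$delta_max_interior)) " (interior maximum)"
          else " (H monotone on [0, 1])", "\n", sep = "")
    cat("  max total: ", fmt(x$max_total), " at delta = ",
        fmt(x$argmax_delta), "\n", sep = "")
    if (!is.null(x$kappa)) cat("  kappa_d:   ", fmt(x$kappa), "\n", sep = "")
  } else {
    cat("  H_c(inf):  ", fmt(x$H_inf), "\n", sep = "")
    cat("  large-dispersal slope criterion: ",
        fmt(x$Hprime_inf_criterion), "\n", sep = "")
    cat("  kappa_c:   ", fmt(x$kappa_c), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a closed-form summary to JSON
#'
#' Stable field names so downstream tools (and the command-line interface)
#' can rely on the layout.
#'
#' @param x a [summary.two_patch()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
summary_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "summary.two_patch"))
  payload <- list(
    mode = x$mode,
    parameters = as.list(coef(x$model)),
    swapped = x$swapped,
    label = x$classification$label,
    boundary = x$classification$boundary)
  for (nm in c("delta_tilde", "delta_max", "Nbar_A", "Nbar_B",
               "H_prime_zero", "max_total", "argmax_delta", "kappa",
               "kappa_c", "H_inf", "Hprime_inf_criterion"))
    if (!is.null(x[[nm]])) payload[[nm]] <- x[[nm]]
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
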