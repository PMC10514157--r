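#' Construct a two-patch population model
#'
#' Creates a model object describing two habitat patches coupled by
#' symmetric dispersal. Each patch is characterised by an intrinsic growth
#' rate \eqn{r_i} and a carrying capacity \eqn{K_i}. Local dynamics are
#' Beverton-Holt in discrete time or logistic in continuous time; both
#' patches are assumed to be sources, i.e. each isolated patch converges to
#' its carrying capacity.
#'
#' The dispersal rate itself is not part of the model object: all analysis
#' functions take it as an argument, because the object of study is the
#' response of the asymptotic total population size to varying dispersal.
#'
#' @param r_A,r_B intrinsic growth rates. In discrete mode these are
#'   per-generation multipliers and must exceed 1; in continuous mode they
#'   are per-capita rates and must be positive.
#' @param K_A,K_B carrying capacities (individuals), strictly positive.
#' @param mode `"discrete"` (Beverton-Holt map) or `"continuous"`
#'   (logistic ODE).
#' @return An object of class `"two_patch"`: a list with elements `r_A`,
#'   `r_B`, `K_A`, `K_B` and `mode`.
#' @seealso [equilibrium()], [response_curve()], [classify()],
#'   [summary.two_patch()]
#' @examples
#' m <- two_patch(r_A = 3, r_B = 1.5, K_A = 2, K_B = 1.5)
#' m
#' coef(m)
#' @export
two_patch <- function(r_A, r_B, K_A, K_B, mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  for (nm in c("r_A", "r_B", "K_A", "K_B")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (K_A <= 0 || K_B <= 0)
    stop("carrying capacities must be strictly positive", call. = FALSE)
  if (mode == "discrete" && (r_A <= 1 || r_B <= 1))
    stop("discrete mode requires source patches: r_A > 1 and r_B > 1",
         call. = FALSE)
  if (mode == "continuous" && (r_A <= 0 || r_B <= 0))
    stop("continuous mode requires source patches: r_A > 0 and r_B > 0",
         call. = FALSE)
  structure(list(r_A = r_A, r_B = r_B, K_A = K_A, K_B = K_B, mode = mode),
            class = "two_patch")
}

is_two_patch <- function(x) inherits(x, "two_patch")

assert_two_patch <- function(x, mode = NULL) {
  if (!is_two_patch(x)) stop("expected a 'two_patch' model object", call. = FALSE)
  if (!is.null(mode) && x$mode != mode)
    stop("this operation requires a model in ", mode, " mode", call. = FALSE)
  invisible(x)
}

#' Intraspecific competition strengths
#'
#' The composite density-dependence parameter of each patch:
#' \eqn{\xi_i = (r_i - 1)/K_i} for the Beverton-Holt map and
#' \eqn{\xi_i = r_i/K_i} for the logistic model. It is always derived from
#' `r` and `K`, never stored, so the three quantities cannot fall out of
#' sync.
#'
#' @param model a [two_patch()] model.
#' @return Named numeric vector `c(xi_A =, xi_B =)`, both strictly positive.
#' @examples
#' xi(two_patch(3, 1.5, 2, 1.5))
#' @export
xi <- function(model) {
  assert_two_patch(model)
  if (model$mode == "discrete") {
    c(xi_A = (model$r_A - 1) / model$K_A, xi_B = (model$r_B - 1) / model$K_B)
  } else {
    c(xi_A = model$r_A / model$K_A, xi_B = model$r_B / model$K_B)
  }
}

#' @export
print.two_patch <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat("Two-patch ", x$mode, "-time model (",
      if (x$mode == "discrete") "Beverton-Holt" else "logistic", " growth)\n",
      sep = "")
  xs <- xi(x)
  cat(sprintf("  patch A: r = %s, K = %s, xi = %s\n",
              format(x$r_A, digits = digits), format(x$K_A, digits = digits),
              format(xs[["xi_A"]], digits = digits)))
  cat(sprintf("  patch B: r = %s, K = %s, xi = %s\n",
              format(x$r_B, digits = digits), format(x$K_B, digits = digits),
              format(xs[["xi_B"]], digits = digits)))
  cat("  admissible dispersal: ",
      if (x$mode == "discrete") "delta in [0, 1]" else "delta_c >= 0", "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.two_patch <- function(object, ...) {
  c(r_A = object$r_A, r_B = object$r_B,
    K_A = object$K_A, K_B = object$K_B)
}

# validate a state vector (N_A, N_B); used by every dynamic operation so
# that divergence bugs surface at the call site
check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 2L)
    stop("state must be a numeric vector (N_A, N_B)", call. = FALSE)
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and non-negative", call. = FALSE)
  invisible(state)
}

#' Swap the patch labels of a model
#'
#' Relabels patch A as patch B and vice versa. The model family is
#' symmetric under this relabeling, which the canonical orientation used by
#' the classifiers relies on.
#'
#' @param model a [two_patch()] model.
#' @return A `two_patch` model with the two patches exchanged.
#' @export
swap_patches <- function(model) {
  assert_two_patch(model)
  two_patch(r_A = model$r_B, r_B = model$r_A,
            K_A = model$K_B, K_B = model$K_A, mode = model$mode)
}
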