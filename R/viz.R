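#' Graphical equilibrium construction for the discrete map
#'
#' At equilibrium the two points \eqn{(N_A^*, f_A^*)} and
#' \eqn{(N_B^*, f_B^*)} on the two growth curves satisfy two conditions:
#' the growth surpluses cancel (\eqn{f_B^* - N_B^* = -(f_A^* - N_A^*)}),
#' and the chord connecting them has slope \eqn{1/(1 - 2\delta)}. The
#' chord's intersection with the identity line equals half the asymptotic
#' total population size, and the difference between overcrowding in the
#' smaller patch and undercrowding in the larger patch equals
#' \eqn{H(\delta)}.
#'
#' @param model a [two_patch()] model in discrete mode.
#' @param delta dispersal rate in `[0, 1]`.
#' @return List with elements `slope` (`Inf` at the vertical
#'   `delta = 0.5` chord, tagged by `vertical = TRUE`), `vertical`,
#'   `chord` (2x2 matrix, rows `(N*, f*)` for patches A and B),
#'   `half_total_intersection`, `overcrowding`, `undercrowding` and
#'   `residual_eq_balance` (the growth-surplus cancellation residual).
#'   Over- and undercrowding are reported in the canonical orientation
#'   where patch B has the larger carrying capacity.
#' @examples
#' graphical_construction(two_patch(2, 1.25, 1, 1.25), delta = 0.25)$slope
#' @export
graphical_construction <- function(model, delta) {
  assert_two_patch(model, "discrete")
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  # canonical K_B > K_A for the crowding decomposition
  swapped <- model$K_B < model$K_A
  m <- if (swapped) swap_patches(model) else model
  eq <- equilibrium(m, delta)
  f_star <- growth_map(m, eq)
  vertical <- (delta == 0.5)
  slope <- if (vertical) Inf else 1 / (1 - 2 * delta)
  chord <- rbind(A = c(N = unname(eq[1L]), f = f_star[1L]),
                 B = c(N = unname(eq[2L]), f = f_star[2L]))
  # chord-identity intersection: for the vertical chord both equilibrium
  # components coincide, so the intersection is that common value
  half_total <- if (vertical || abs(eq[1L] - eq[2L]) < 1e-12) {
    unname((eq[1L] + eq[2L]) / 2)
  } else {
    s <- (f_star[2L] - f_star[1L]) / (eq[2L] - eq[1L])
    unname((f_star[1L] - s * eq[1L]) / (1 - s))
  }
  list(slope = slope, vertical = vertical, chord = chord,
       half_total_intersection = half_total,
       overcrowding = unname(eq[1L] - m$K_A),
       undercrowding = unname(m$K_B - eq[2L]),
       residual_eq_balance = unname((f_star[2L] - eq[2L]) +
                                      (f_star[1L] - eq[1L])),
       swapped = swapped)
}

#' Population size of maximal per-step growth
#'
#' The point on the Beverton-Holt reproduction curve where the one-step
#' growth \eqn{f(N) - N} is largest,
#' \eqn{N^\blacklozenge = (\sqrt r - 1)/\xi = K/(\sqrt r + 1)}, used to
#' visualise the strength of intraspecific competition. Always strictly
#' below the carrying capacity.
#'
#' @param r intrinsic growth rate, must exceed 1.
#' @param K carrying capacity, strictly positive.
#' @return The maximising population size.
#' @examples
#' n_diamond(r = 4, K = 3)  # 1
#' @export
n_diamond <- function(r, K) {
  if (r <= 1 || K <= 0)
    stop("n_diamond requires r > 1 and K > 0", call. = FALSE)
  K / (sqrt(r) + 1)
}

#' Seeded generator of parameter sets inside a scenario region
#'
#' Draws demographic parameters uniformly from given ranges and keeps the
#' draws whose analytic classification matches `target_label` (when set)
#' and that are not flagged as boundary cases. Fully deterministic given
#' `seed`. For the neutral target, equal carrying capacities are enforced
#' by construction (the region has measure zero under independent draws).
#'
#' @param n number of parameter sets to return.
#' @param mode `"discrete"` or `"continuous"`.
#' @param target_label optional scenario label to condition on.
#' @param r_range,K_range ranges for the uniform draws of growth rates and
#'   carrying capacities. Defaults respect the source-patch constraint of
#'   the mode.
#' @param seed integer seed; fully determines the output.
#' @param range dispersal range for discrete classification (see
#'   [classify()]).
#' @param boundary_margin draws whose defining inequalities sit within
#'   this relative margin of equality are rejected, keeping the sample
#'   clear of region boundaries.
#' @param max_tries rejection-sampling budget; if the acceptance rate
#'   falls below roughly `1e-4` the region is reported as empty.
#' @return List of `n` [two_patch()] models.
#' @examples
#' ps <- generate_scenario_params(3, "discrete",
#'                                target_label = "monotonically_detrimental",
#'                                seed = 1)
#' sapply(ps, function(m) classify(m)$label)
#' @export
generate_scenario_params <- function(n, mode = c("discrete", "continuous"),
                                     target_label = NULL,
                                     r_range = NULL, K_range = c(0.5, 5),
                                     seed = 1L, range = "full",
                                     boundary_margin = 1e-3,
                                     max_tries = NULL) {
  mode <- match.arg(mode)
  if (!is.null(target_label))
    target_label <- match.arg(target_label, scenario_labels)
  if (is.null(r_range))
    r_range <- if (mode == "discrete") c(1.1, 4) else c(0.2, 3)
  if (is.null(max_tries)) max_tries <- max(10000L, n * 10000L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  got <- 0L
  for (i in seq_len(max_tries)) {
    r <- stats::runif(2, r_range[1L], r_range[2L])
    K <- stats::runif(2, K_range[1L], K_range[2L])
    if (identical(target_label, "neutral_equal_K")) K[2L] <- K[1L]
    m <- tryCatch(two_patch(r[1L], r[2L], K[1L], K[2L], mode),
                  error = function(e) NULL)
    if (is.null(m)) next
    cls <- classify(m, range = range, rel_tol = boundary_margin)
    if (cls$boundary) next
    if (!is.null(target_label) && cls$label != target_label) next
    got <- got + 1L
    out[[got]] <- m
    if (got == n) return(out)
  }
  stop("scenario region appears empty: accepted ", got, " of ", max_tries,
       " draws", call. = FALSE)
}

#' Plot a dispersal response curve
#'
#' Total asymptotic population size against the dispersal rate, with a
#' dashed horizontal line at the sum of the carrying capacities, a grey
#' vertical guide at the perfect-mixing rate `delta = 0.5` (discrete mode),
#' and a cross at the maximum.
#'
#' @param x a [response_curve()] object.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.response_curve <- function(x, ...) {
  model <- attr(x, "model")
  KK <- if (!is.null(model)) model$K_A + model$K_B else NULL
  total <- x$N_A + x$N_B
  args <- list(x = x$delta, y = total, type = "l", lwd = 2,
               xlab = if (attr(x, "mode") == "discrete")
                 expression(delta) else expression(delta[c]),
               ylab = "asymptotic total population size")
  extra <- list(...)
  args[names(extra)] <- extra
  if (attr(x, "mode") == "continuous" && is.null(extra$log) &&
      max(x$delta) / max(x$delta[2L], 1e-12) > 1e3)
    args$x <- x$delta  # keep linear axis; caller may pass log = "x"
  do.call(graphics::plot, args)
  if (!is.null(KK)) graphics::abline(h = KK, lty = 2)
  if (attr(x, "mode") == "discrete")
    graphics::abline(v = 0.5, col = "grey70")
  i <- which.max(total)
  graphics::points(x$delta[i], total[i], pch = 4, col = "red", cex = 1.4,
                   lwd = 2)
  invisible(x)
}

#' @export
plot.two_patch <- function(x, grid = NULL, points = 201L, ...) {
  plot(response_curve(x, grid = grid, points = points), ...)
}
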