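#' Positive equilibrium of the coupled two-patch system
#'
#' Computes the unique positive attractor of the dynamics at a fixed
#' dispersal rate. In discrete mode the coupled Beverton-Holt map has a
#' unique positive fixed point that attracts every non-trivial initial
#' state, so the map is iterated from the carrying capacities and the
#' result is polished with Newton steps on the fixed-point residual. In
#' continuous mode the system is integrated until the vector field is
#' small, then polished with Newton steps on the vector field (the
#' integration is skipped when a warm start is supplied).
#'
#' @param model a [two_patch()] model.
#' @param delta dispersal rate: in `[0, 1]` for discrete mode,
#'   non-negative for continuous mode.
#' @param tol convergence tolerance (sup-norm of the residual).
#' @param max_iter iteration cap for the discrete map.
#' @param init optional warm-start state for the Newton polish
#'   (continuous mode); used when sweeping a grid of dispersal rates.
#' @return Named numeric vector `c(N_A =, N_B =)`.
#' @examples
#' m <- two_patch(3, 1.5, 2, 1.5)
#' equilibrium(m, delta = 0)    # carrying capacities
#' equilibrium(m, delta = 1)    # complete replacement: c(1.75, 21/11)
#' @export
equilibrium <- function(model, delta, tol = 1e-12, max_iter = 1e6,
                        init = NULL) {
  assert_two_patch(model)
  if (model$mode == "discrete") {
    equilibrium_discrete(model, delta, tol = tol, max_iter = max_iter,
                         init = init)
  } else {
    equilibrium_continuous(model, delta, tol = tol, init = init)
  }
}

equilibrium_discrete <- function(model, delta, tol = 1e-12, max_iter = 1e6,
                                 init = NULL) {
  assert_two_patch(model, "discrete")
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  if (!is.null(init)) {
    # warm start (grid sweeps): Newton from the neighbouring solution,
    # falling back to the globally convergent iteration on failure
    polished <- tryCatch(
      newton_polish_discrete(model, init, delta, tol = tol),
      error = function(e) NULL)
    if (!is.null(polished) &&
        all(polished > 1e-8 * (model$K_A + model$K_B)))
      return(polished)
  }
  x <- c(model$K_A, model$K_B)
  # crude iteration: globally convergent, switches to Newton once close
  for (i in seq_len(max_iter)) {
    x_new <- step_discrete(model, x, delta)
    if (max(abs(x_new - x)) < 1e-8) { x <- x_new; break }
    x <- x_new
    if (i == max_iter)
      stop("discrete equilibrium iteration did not converge", call. = FALSE)
  }
  newton_polish_discrete(model, x, delta, tol = tol)
}

# Newton on g(x) = step(x) - x with the analytic Jacobian of the map
newton_polish_discrete <- function(model, x, delta, tol = 1e-12,
                                   max_newton = 50L) {
  for (i in seq_len(max_newton)) {
    fpA <- beverton_holt_deriv(x[1L], model$r_A, model$K_A)
    fpB <- beverton_holt_deriv(x[2L], model$r_B, model$K_B)
    J <- rbind(c((1 - delta) * fpA - 1, delta * fpB),
               c(delta * fpA, (1 - delta) * fpB - 1))
    g <- step_discrete(model, x, delta) - x
    if (max(abs(g)) < tol) break
    dx <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(dx)) break
    x_new <- x + dx
    if (any(x_new <= 0)) break  # fall back to the iterated value
    x <- x_new
  }
  res <- step_discrete(model, x, delta) - x
  if (max(abs(res)) > 1e-9)
    stop("discrete equilibrium polish did not converge (residual ",
         format(max(abs(res))), ")", call. = FALSE)
  c(N_A = x[1L], N_B = x[2L])
}

equilibrium_continuous <- function(model, delta_c, tol = 1e-12, init = NULL) {
  assert_two_patch(model, "continuous")
  if (delta_c < 0) stop("delta_c must be non-negative", call. = FALSE)
  if (delta_c == 0)
    return(c(N_A = model$K_A, N_B = model$K_B))
  if (!is.null(init)) {
    polished <- tryCatch(
      newton_polish_continuous(model, init, delta_c, tol = tol),
      error = function(e) NULL)
    if (!is.null(polished) &&
        all(polished > 1e-8 * (model$K_A + model$K_B)))
      return(polished)
  }
  x <- integrate_to_rest(model, delta_c)
  newton_polish_continuous(model, x, delta_c, tol = tol)
}

# integrate from the carrying capacities until the field norm is small;
# lsoda copes with the stiffness induced by large dispersal rates
integrate_to_rest <- function(model, delta_c, field_tol = 1e-9,
                              t_chunk = 50, max_chunks = 200L) {
  rhs <- function(t, y, parms) list(vector_field_continuous(model, y, delta_c))
  x <- c(model$K_A, model$K_B)
  for (k in seq_len(max_chunks)) {
    sol <- deSolve::ode(y = x, times = c(0, t_chunk), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    x <- unname(sol[nrow(sol), 2:3])
    if (max(abs(vector_field_continuous(model, x, delta_c))) < field_tol)
      return(x)
  }
  stop("continuous-time integration did not settle", call. = FALSE)
}

newton_polish_continuous <- function(model, x, delta_c, tol = 1e-12,
                                     max_newton = 100L) {
  for (i in seq_len(max_newton)) {
    g <- vector_field_continuous(model, x, delta_c)
    if (max(abs(g)) < tol) break
    J <- rbind(c(logistic_rate_deriv(x[1L], model$r_A, model$K_A) - delta_c,
                 delta_c),
               c(delta_c,
                 logistic_rate_deriv(x[2L], model$r_B, model$K_B) - delta_c))
    dx <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(dx)) break
    # damped step: keep the iterate strictly positive
    step_scale <- 1
    while (any(x + step_scale * dx <= 0) && step_scale > 1e-6)
      step_scale <- step_scale / 2
    x <- x + step_scale * dx
  }
  res <- vector_field_continuous(model, x, delta_c)
  if (max(abs(res)) > 1e-8 * max(1, delta_c))
    stop("continuous steady-state solve did not converge (residual ",
         format(max(abs(res))), ")", call. = FALSE)
  c(N_A = x[1L], N_B = x[2L])
}

#' Dispersal-response function H
#'
#' The difference between the asymptotic total population size of the
#' connected patches and the sum of the carrying capacities:
#' \deqn{H(\delta) = N_A(\delta) + N_B(\delta) - (K_A + K_B).}
#' Dispersal is beneficial where `H > 0` and detrimental where `H < 0`.
#' `H(0)` is returned as exactly zero by definition, avoiding cancellation
#' noise at the anchor point.
#'
#' @inheritParams equilibrium
#' @return The response value (individuals), same units as the carrying
#'   capacities.
#' @examples
#' m <- two_patch(3, 1.5, 2, 1.5)
#' H_dispersal(m, 0)      # exactly 0
#' H_dispersal(m, 1) > 0  # monotonically beneficial parameters
#' @export
H_dispersal <- function(model, delta, tol = 1e-12, init = NULL) {
  assert_two_patch(model)
  if (delta == 0) return(0)
  eq <- equilibrium(model, delta, tol = tol, init = init)
  unname(eq[1L] + eq[2L] - (model$K_A + model$K_B))
}

#' Default dispersal grid for a model
#'
#' Discrete mode: `points` equally spaced rates on `[0, 1]`. Continuous
#' mode: zero followed by log-spaced rates from `10^-4` to `10^4`; the
#' logarithmic spacing resolves the small-dispersal behaviour (where the
#' response function can change sign very close to zero) as well as the
#' perfect-mixing limit at large rates.
#'
#' @param model a [two_patch()] model.
#' @param points total number of grid points.
#' @return Strictly increasing numeric vector starting at 0.
#' @export
default_grid <- function(model, points = 201L) {
  assert_two_patch(model)
  if (model$mode == "discrete") {
    seq(0, 1, length.out = points)
  } else {
    c(0, 10^seq(-4, 4, length.out = points - 1L))
  }
}

#' Equilibrium response curve over a dispersal grid
#'
#' Evaluates the equilibrium state and the response function H at every
#' point of a dispersal grid. Grid points are solved in order with warm
#' starts, which makes continuous-mode sweeps cheap even into the
#' large-dispersal tail.
#'
#' @param model a [two_patch()] model.
#' @param grid strictly increasing vector of dispersal rates starting at 0;
#'   defaults to [default_grid()].
#' @param points grid size used when `grid` is `NULL`.
#' @return An object of class `"response_curve"`: a data frame with columns
#'   `delta`, `N_A`, `N_B`, `H` and attributes `mode` and `model`.
#' @examples
#' m <- two_patch(3, 1.5, 2, 1.5)
#' rc <- response_curve(m, points = 51)
#' head(rc)
#' @export
response_curve <- function(model, grid = NULL, points = 201L) {
  assert_two_patch(model)
  if (is.null(grid)) grid <- default_grid(model, points)
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE) || grid[1L] != 0)
    stop("grid must be strictly increasing and start at 0", call. = FALSE)
  if (model$mode == "discrete" && grid[length(grid)] > 1)
    stop("discrete-mode grid must lie in [0, 1]", call. = FALSE)
  n <- length(grid)
  NA_mat <- matrix(NA_real_, n, 2L)
  prev <- NULL
  for (i in seq_len(n)) {
    eq <- tryCatch(
      equilibrium(model, grid[i], init = prev),
      error = function(e) stop("equilibrium failed at dispersal rate ",
                               format(grid[i]), ": ", conditionMessage(e),
                               call. = FALSE))
    NA_mat[i, ] <- eq
    prev <- unname(eq)
  }
  H <- NA_mat[, 1L] + NA_mat[, 2L] - (model$K_A + model$K_B)
  H[grid == 0] <- 0  # anchor value is exact by definition
  structure(
    data.frame(delta = grid, N_A = NA_mat[, 1L], N_B = NA_mat[, 2L], H = H),
    mode = model$mode, model = model,
    class = c("response_curve", "data.frame"))
}

#' Numerically locate the maximum of H
#'
#' Coarse grid scan followed by golden-section refinement
#' ([stats::optimize()]) on the bracketing subinterval. Valid because H is
#' either strictly monotone or unimodal on the admissible dispersal range;
#' when H is monotone the appropriate endpoint is returned.
#'
#' @param model a [two_patch()] model.
#' @param interval dispersal interval to search; defaults to `[0, 1]`
#'   (discrete) or `[0, 100]` (continuous).
#' @param coarse_points size of the seeding scan.
#' @param tol tolerance passed to the golden-section refinement.
#' @return List with elements `delta` (argmax) and `H` (value there).
#' @examples
#' m <- two_patch(3.2, 1.5, 3.85, 1.37)
#' numeric_argmax_H(m)
#' @export
numeric_argmax_H <- function(model, interval = NULL, coarse_points = 101L,
                             tol = 1e-10) {
  assert_two_patch(model)
  if (is.null(interval))
    interval <- if (model$mode == "discrete") c(0, 1) else c(0, 100)
  if (model$mode == "discrete")
    interval <- pmin(pmax(interval, 0), 1)
  grid <- seq(interval[1L], interval[2L], length.out = coarse_points)
  vals <- vapply(grid, function(d) H_dispersal(model, d), numeric(1))
  i <- which.max(vals)  # which.max takes the first maximum: ties break small
  if (i == 1L || i == coarse_points) {
    # maximum at (or hugging) an endpoint: H monotone near it
    return(list(delta = grid[i], H = vals[i]))
  }
  opt <- stats::optimize(function(d) H_dispersal(model, d),
                         lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = tol)
  list(delta = opt$maximum, H = opt$objective)
}

#' Numerically locate the non-trivial zero of H
#'
#' H always vanishes at zero dispersal and can have at most one further
#' zero. This scans a grid for a sign change and refines it by root
#' bracketing ([stats::uniroot()]).
#'
#' @param model a [two_patch()] model.
#' @param interval search interval excluding 0; defaults to `(0, 1]`
#'   (discrete) or `(0, 100]` (continuous).
#' @param coarse_points size of the scanning grid.
#' @param tol root tolerance.
#' @return The dispersal rate of the sign change, or `NULL` when H has
#'   constant sign on the interval.
#' @examples
#' m <- two_patch(3.4, 1.5, 8.4, 1.37)
#' numeric_zero_H(m)  # about 0.3748
#' @export
numeric_zero_H <- function(model, interval = NULL, coarse_points = 201L,
                           tol = 1e-10) {
  assert_two_patch(model)
  if (is.null(interval))
    interval <- if (model$mode == "discrete") c(1e-4, 1) else c(1e-4, 100)
  grid <- seq(interval[1L], interval[2L], length.out = coarse_points)
  vals <- vapply(grid, function(d) H_dispersal(model, d), numeric(1))
  noise <- 1e-10 * max(1, model$K_A + model$K_B)
  sgn <- sign(vals) * (abs(vals) > noise)
  change <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(change) == 0L) return(NULL)
  j <- change[1L]  # at most one non-trivial zero; take the first bracket
  stats::uniroot(function(d) H_dispersal(model, d),
                 lower = grid[j], upper = grid[j + 1L], tol = tol)$root
}

#' @export
print.response_curve <- function(x, ...) {
  cat("Dispersal response curve (", attr(x, "mode"), " mode, ",
      nrow(x), " grid points)\n", sep = "")
  cat("  H range: [", format(min(x$H), digits = 6), ", ",
      format(max(x$H), digits = 6), "]\n", sep = "")
  NextMethod()
}

#' Predicted equilibrium at given dispersal rates
#'
#' @param object a [two_patch()] model.
#' @param delta vector of dispersal rates.
#' @param ... unused.
#' @return Data frame with columns `delta`, `N_A`, `N_B`, `H`.
#' @export
predict.two_patch <- function(object, delta, ...) {
  out <- t(vapply(delta, function(d) {
    eq <- equilibrium(object, d)
    c(eq, H = if (d == 0) 0 else
      unname(eq[1L] + eq[2L] - (object$K_A + object$K_B)))
  }, numeric(3)))
  data.frame(delta = delta, N_A = out[, 1L], N_B = out[, 2L], H = out[, 3L])
}

#' Write / read a response curve as CSV
#'
#' Plain CSV with the fixed header `delta, N_A, N_B, H`. Values are written
#' at full double precision so a round trip reproduces the curve exactly.
#'
#' @param curve a [response_curve()] object.
#' @param path file path.
#' @param mode the time mode to attach on reading.
#' @return `write_response_curve` returns `path` invisibly;
#'   `read_response_curve` returns a `response_curve` object.
#' @export
write_response_curve <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  df <- as.data.frame(curve)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' JSON summary of a response curve
#'
#' Compact description of a computed curve: grid extent, extreme H values
#' and where they occur, and whether the curve changes sign.
#'
#' @param curve a [response_curve()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
curve_summary_json <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "response_curve"))
  i_max <- which.max(curve$H)
  i_min <- which.min(curve$H)
  payload <- list(
    mode = attr(curve, "mode"),
    n_points = nrow(curve),
    delta_range = range(curve$delta),
    H_max = curve$H[i_max], argmax_delta = curve$delta[i_max],
    H_min = curve$H[i_min], argmin_delta = curve$delta[i_min],
    sign_change = any(curve$H > 1e-10) && any(curve$H < -1e-10))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname write_response_curve
#' @export
read_response_curve <- function(path, mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path)
  if (!identical(names(df), c("delta", "N_A", "N_B", "H")))
    stop("unexpected response-curve columns in ", path, call. = FALSE)
  structure(df, mode = mode, class = c("response_curve", "data.frame"))
}
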