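#' Beverton-Holt growth function
#'
#' One generation of density-dependent growth,
#' \eqn{f(N) = rN / (1 + \xi N)} with \eqn{\xi = (r-1)/K}. The map is
#' strictly increasing in `N`, bounded above by \eqn{r/\xi}, and has the
#' carrying capacity `K` as its unique positive fixed point.
#'
#' @param N population size, non-negative. Vectorised.
#' @param r intrinsic growth rate (per-generation multiplier), must exceed 1.
#' @param K carrying capacity, strictly positive.
#' @return Population size after one generation of local growth.
#' @examples
#' beverton_holt(1, r = 3, K = 2)  # 1.5
#' beverton_holt(2, r = 3, K = 2)  # K is a fixed point
#' @export
beverton_holt <- function(N, r, K) {
  if (r <= 1 || K <= 0)
    stop("Beverton-Holt growth requires r > 1 and K > 0", call. = FALSE)
  if (any(!is.finite(N)) || any(N < 0))
    stop("N must be finite and non-negative", call. = FALSE)
  r * N / (1 + (r - 1) / K * N)
}

# derivative of the Beverton-Holt map in N; used by Newton polishing
beverton_holt_deriv <- function(N, r, K) {
  r / (1 + (r - 1) / K * N)^2
}

#' Logistic growth rate
#'
#' Instantaneous per-capita logistic growth,
#' \eqn{f(N) = rN(1 - N/K)}, zero at \eqn{N = 0} and \eqn{N = K}.
#'
#' @param N population size, non-negative. Vectorised.
#' @param r intrinsic growth rate, strictly positive.
#' @param K carrying capacity, strictly positive.
#' @return Rate of change of the population size.
#' @examples
#' logistic_rate(1, r = 2, K = 2)  # 1
#' logistic_rate(2, r = 2, K = 2)  # equilibrium
#' @export
logistic_rate <- function(N, r, K) {
  if (r <= 0 || K <= 0)
    stop("logistic growth requires r > 0 and K > 0", call. = FALSE)
  if (any(!is.finite(N)) || any(N < 0))
    stop("N must be finite and non-negative", call. = FALSE)
  r * N * (1 - N / K)
}

logistic_rate_deriv <- function(N, r, K) {
  r * (1 - 2 * N / K)
}

# patch-wise growth of a state under the model's local dynamics
growth_map <- function(model, state) {
  c(beverton_holt(state[1L], model$r_A, model$K_A),
    beverton_holt(state[2L], model$r_B, model$K_B))
}

growth_rates <- function(model, state) {
  c(logistic_rate(state[1L], model$r_A, model$K_A),
    logistic_rate(state[2L], model$r_B, model$K_B))
}

#' One step of the discrete two-patch map
#'
#' Growth happens first, dispersal second: a fraction `delta` of each
#' patch's post-growth population moves to the other patch. `delta = 0.5`
#' is perfect mixing (the two patches are equal after one iteration);
#' `delta = 1` swaps the patch outputs completely. Dispersal conserves
#' individuals, so the total after the step is
#' \eqn{f_A(N_A) + f_B(N_B)} regardless of `delta`.
#'
#' @param model a [two_patch()] model in discrete mode.
#' @param state numeric vector `(N_A, N_B)`, finite and non-negative.
#' @param delta dispersal rate in `[0, 1]`.
#' @return The state `(N_A, N_B)` at the next time step.
#' @examples
#' m <- two_patch(3, 1.5, 2, 1.5)
#' step_discrete(m, c(2, 1.5), delta = 0.5)
#' @export
step_discrete <- function(model, state, delta) {
  assert_two_patch(model, "discrete")
  check_state(state)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta > 1)
    stop("delta must lie in [0, 1]", call. = FALSE)
  f <- growth_map(model, state)
  c((1 - delta) * f[1L] + delta * f[2L],
    (1 - delta) * f[2L] + delta * f[1L])
}

#' Vector field of the continuous two-patch model
#'
#' Right-hand side of the coupled logistic system: local logistic growth
#' plus symmetric linear dispersal at rate `delta_c`. The two dispersal
#' fluxes are antisymmetric, so the sum of the components equals
#' \eqn{f_A(N_A) + f_B(N_B)}: dispersal moves individuals but never creates
#' or destroys them.
#'
#' @param model a [two_patch()] model in continuous mode.
#' @param state numeric vector `(N_A, N_B)`, finite and non-negative.
#' @param delta_c dispersal rate, non-negative.
#' @return Numeric vector of the two time derivatives.
#' @examples
#' m <- two_patch(1, 2, 0.5, 1.5, mode = "continuous")
#' vector_field_continuous(m, c(0.5, 1.5), delta_c = 0)  # c(0, 0)
#' @export
vector_field_continuous <- function(model, state, delta_c) {
  assert_two_patch(model, "continuous")
  check_state(state)
  if (!is.numeric(delta_c) || length(delta_c) != 1L || !is.finite(delta_c) ||
      delta_c < 0)
    stop("delta_c must be non-negative", call. = FALSE)
  f <- growth_rates(model, state)
  flux <- delta_c * (state[1L] - state[2L])
  c(f[1L] - flux, f[2L] + flux)
}

#' Simulate trajectories of a two-patch model
#'
#' Iterates the discrete map or integrates the continuous system from a
#' given initial state at a fixed dispersal rate.
#'
#' @param object a [two_patch()] model.
#' @param nsim number of time steps (discrete) or output time points
#'   (continuous).
#' @param seed unused (the dynamics are deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param delta dispersal rate (in `[0, 1]` for discrete mode,
#'   non-negative for continuous mode).
#' @param init initial state `(N_A, N_B)`; defaults to the carrying
#'   capacities.
#' @param tmax final time for continuous mode (ignored in discrete mode).
#' @param ... unused.
#' @return A data frame with columns `time`, `N_A`, `N_B`, `N_tot`.
#' @examples
#' m <- two_patch(3, 1.5, 2, 1.5)
#' tail(simulate(m, nsim = 50, delta = 0.3))
#' @export
simulate.two_patch <- function(object, nsim = 100, seed = NULL, delta,
                               init = NULL, tmax = 50, ...) {
  if (is.null(init)) init <- c(object$K_A, object$K_B)
  check_state(init)
  if (object$mode == "discrete") {
    out <- matrix(NA_real_, nrow = nsim + 1L, ncol = 2L)
    out[1L, ] <- init
    for (t in seq_len(nsim))
      out[t + 1L, ] <- step_discrete(object, out[t, ], delta)
    time <- 0:nsim
  } else {
    rhs <- function(t, y, parms) list(vector_field_continuous(object, y, delta))
    time <- seq(0, tmax, length.out = nsim + 1L)
    sol <- deSolve::ode(y = init, times = time, func = rhs, parms = NULL,
                        method = "lsoda")
    out <- unname(sol[, 2:3, drop = FALSE])
  }
  data.frame(time = time, N_A = out[, 1L], N_B = out[, 2L],
             N_tot = out[, 1L] + out[, 2L])
}
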