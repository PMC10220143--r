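## Deterministic (noise-free) recombination dynamics.  These have closed
## forms and serve as analytic oracles for the estimator and information
## code: on the mutation-free deterministic path the raw estimator recovers
## the true rate exactly in the continuous-time limit, and the information
## admits a closed form with a finite limit as T grows.

#' Closed-form deterministic recombination dynamics
#'
#' Without mutation or noise the haplotype frequencies obey
#' \eqn{dx_{ij}/dt = \rho(x_{i\cdot}x_{\cdot j} - x_{ij})}; the allele
#' marginals are conserved and the solution relaxes exponentially to
#' linkage equilibrium:
#' \deqn{x_{ij}(t) = x_{ij}(0)e^{-\rho t} +
#'   x_{i\cdot}(0)x_{\cdot j}(0)(1 - e^{-\rho t}).}
#'
#' @param x0 initial frequency vector (stacked, length \eqn{KL}).
#' @param rho recombination rate (\eqn{\ge 0}).
#' @param t time (vector allowed).
#' @param K,L allele counts (inferred for \eqn{d = 4}).
#' @return for scalar \code{t} a frequency vector; for vector \code{t} a
#'   \code{length(t)} \eqn{\times\, d} matrix.
#' @examples
#' ode_solution(c(0.4, 0.2, 0.2, 0.2), rho = 5, t = Inf)  # product of marginals
#' @export
ode_solution <- function(x0, rho, t, K = NULL, L = NULL) {
  kl <- infer_KL(x0, K, L)
  m <- marginal_product(x0, kl[1], kl[2])
  e <- exp(-rho * t)
  out <- outer(e, x0) + outer(1 - e, m)
  if (length(t) == 1L) drop(out) else out
}

#' Closed-form deterministic information
#'
#' Along the deterministic recombination path the observed information has
#' the closed form (for \eqn{\rho > 0})
#' \deqn{I_T = \rho^{-1}\sum_{ij} x_{i\cdot}(0)x_{\cdot j}(0)
#'   \log\big(x_{ij}(T)/x_{ij}(0)\big),}
#' increasing in \eqn{T} with the finite limit
#' \eqn{\rho^{-1}\sum_{ij} x_{i\cdot}(0)x_{\cdot j}(0)
#'   \log\big(x_{i\cdot}(0)x_{\cdot j}(0)/x_{ij}(0)\big)}: a deterministic
#' trajectory only carries information during its transient phase.
#'
#' @inheritParams ode_solution
#' @param t_end horizon \eqn{T} (\code{Inf} gives the limit).
#' @return scalar information.
#' @export
info_closed_form <- function(x0, rho, t_end, K = NULL, L = NULL) {
  if (rho <= 0) stop("closed form requires rho > 0")
  kl <- infer_KL(x0, K, L)
  check_freq(x0, interior = TRUE)
  m <- marginal_product(x0, kl[1], kl[2])
  xT <- if (is.infinite(t_end)) m else ode_solution(x0, rho, t_end, kl[1], kl[2])
  sum(m * log(xT / x0)) / rho
}

#' @rdname info_closed_form
#' @export
info_limit <- function(x0, rho, K = NULL, L = NULL) {
  info_closed_form(x0, rho, Inf, K, L)
}

#' Deterministic path as a trajectory object
#'
#' Evaluates the closed-form dynamics on a uniform grid and wraps the result
#' as a \code{"wf_path"} (mutation-free model), so the path-functional and
#' estimator code can be run on an analytically known input.
#'
#' @inheritParams ode_solution
#' @param t_end horizon.
#' @param dt grid step.
#' @return a \code{"wf_path"} without streamed functionals (estimators
#'   recompute from the grid).
#' @export
deterministic_path <- function(x0, rho, t_end = 1, dt = 1e-4,
                               K = NULL, L = NULL) {
  kl <- infer_KL(x0, K, L)
  tt <- seq(0, t_end, by = dt)
  X <- ode_solution(x0, rho, tt, kl[1], kl[2])
  model <- wf_model(allele_counts = kl, rho = rho)
  structure(list(times = tt, X = X, dW = NULL, dt = dt, t_end = t_end,
                 model = model, seed = NA_integer_, exploded = FALSE,
                 explosion_step = NA_integer_, explosion_time = NA_real_,
                 functionals = NULL, run = NULL),
            class = "wf_path")
}

#' Estimator evaluated on the deterministic path
#'
#' Runs the raw path estimator on the gridded closed-form trajectory.  In
#' the continuous-time limit the estimator returns the true rate exactly
#' (the compensated increments are exactly \eqn{a(x;\rho)dt}); on a grid the
#' error is \eqn{O(dt)}.
#'
#' @inheritParams deterministic_path
#' @return the raw estimate (numeric scalar).
#' @export
estimator_on_deterministic_path <- function(x0, rho, t_end = 1, dt = 1e-4,
                                            K = NULL, L = NULL) {
  if (rho == 0) return(0)
  p <- deterministic_path(x0, rho, t_end, dt, K, L)
  rho_mle(p, use_streamed = FALSE)$raw
}

#' Deterministic mutation-recombination dynamics (numeric)
#'
#' With mutation present the deterministic system
#' \eqn{dx/dt = c(x) + a(x;\rho)} no longer has the simple exponential
#' solution; this integrates it numerically (classical fourth-order
#' Runge--Kutta on a fixed grid, so no extra dependency is needed) and
#' returns the gridded path as a \code{"wf_path"}.  Its information still
#' converges to a finite limit as the system relaxes to its fixed point.
#'
#' @param model a two-locus \code{"wf_model"} (with mutation).
#' @param x0 initial state.
#' @param t_end horizon.
#' @param dt grid step.
#' @return a \code{"wf_path"}.
#' @export
deterministic_path_mutation <- function(model, x0, t_end = 1, dt = 1e-4) {
  stopifnot(inherits(model, "wf_model"), model$num_loci == 2L)
  nn <- round(t_end / dt)
  X <- matrix(NA_real_, nn + 1L, model$d)
  x <- x0
  X[1, ] <- x
  f <- function(x) drift_total(x, model)
  for (k in seq_len(nn)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    X[k + 1L, ] <- x
  }
  structure(list(times = seq(0, by = dt, length.out = nn + 1L), X = X,
                 dW = NULL, dt = dt, t_end = t_end, model = model,
                 seed = NA_integer_, exploded = FALSE,
                 explosion_step = NA_integer_, explosion_time = NA_real_,
                 functionals = NULL, run = NULL),
            class = "wf_path")
}
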