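## Likelihood functionals of an observed path.
##
## For drift linear in the parameters, a_i(x; phi) = sum_k Z_ik(x) phi_k, the
## log-likelihood relative to the phi_0 = 0 reference measure is the quadratic
##   log L_T(phi) = phi' Y - (1/2) phi' I_T phi,
## with score integrals Y_k = int sum_i Z_ik/X_i dXtilde_i and observed
## information I_kl = int sum_i Z_ik Z_il / X_i dt, where
## Xtilde(t) = X(t) - int_0^t c(X(s)) ds compensates the known drift.
## All stochastic integrals use left-endpoint Riemann sums on the grid
## (the Ito convention matching the Euler-Maruyama discretization).

#' Likelihood functionals of a stored trajectory (two-locus recombination)
#'
#' Recomputes the score integral \eqn{Y}, the observed information \eqn{I_T}
#' (in both its direct \eqn{\sum D^2/x} and expanded
#' \eqn{\sum x_{i\cdot}^2 x_{\cdot j}^2/x - T} forms) and the effective
#' integration horizon from the \emph{stored} grid of a path.  Integration
#' stops at the last grid interval whose right endpoint is strictly interior:
#' once a haplotype frequency hits 0 the information has exploded and
#' \eqn{1/x} is undefined, so the clipped state is excluded (the discrete
#' proxy for the limit \eqn{t \uparrow S}).
#'
#' Paths produced by [simulate.wf_model()] already carry these functionals
#' accumulated at full step resolution; this function is the grid-resolution
#' recomputation used for file-based input, cross-checks and confounder
#' studies (where the compensator model differs from the generating one).
#'
#' @param path a \code{"wf_path"}.
#' @param model the model supplying the known compensator drift \eqn{c}
#'   (mutation, plus selection when \code{selection_known}); defaults to the
#'   model stored with the path.
#' @param selection_known include the model's selection (if any) in the
#'   compensator.
#' @return an object of class \code{"wf_functionals"}: list with \code{Y},
#'   \code{Y_ld_form}, \code{I}, \code{I_expanded}, \code{T_eff},
#'   \code{n_eff}, \code{exploded}, \code{S}.
#' @export
path_functionals <- function(path, model = path$model,
                             selection_known = TRUE) {
  stopifnot(inherits(path, "wf_path"), inherits(model, "wf_model"),
            model$num_loci == 2L)
  X <- path$X
  n <- nrow(X)
  if (n < 2) stop("path has fewer than two stored states")
  dts <- diff(path$times)
  ok <- usable_intervals(path)
  n_eff <- sum(ok)
  exploded <- isTRUE(path$exploded) || n_eff < n - 1L
  if (n_eff == 0) stop("no interior grid interval before the explosion")

  K <- model$K; L <- model$L; d <- model$d
  iA <- rep(seq_len(K), each = L)
  iB <- rep(seq_len(L), times = K)
  IA <- matrix(0, d, K); IA[cbind(seq_len(d), iA)] <- 1
  IB <- matrix(0, d, L); IB[cbind(seq_len(d), iB)] <- 1

  lef <- which(ok)
  XL <- X[lef, , drop = FALSE]
  MA <- XL %*% IA                       # x_{i.} per row
  MB <- XL %*% IB                       # x_{.j} per row
  M <- MA[, iA, drop = FALSE] * MB[, iB, drop = FALSE]
  D <- XL - M
  h <- dts[lef]

  ## compensator at left points
  C <- XL %*% t(mutation_generator(model))
  if (!is.null(model$selection) && isTRUE(selection_known))
    C <- C + t(apply(XL, 1, drift_selection, selection = model$selection,
                     K = K, L = L))
  dX <- X[lef + 1L, , drop = FALSE] - XL
  dXt <- dX - C * h

  Y <- sum((M / XL) * dXt)
  Y_ld <- -sum((D / XL) * dXt)
  I <- sum(rowSums(D^2 / XL) * h)
  T_eff <- sum(h)
  I_exp <- sum(rowSums(M^2 / XL) * h) - T_eff

  structure(list(Y = Y, Y_ld_form = Y_ld, I = I, I_expanded = I_exp,
                 T_eff = T_eff, n_eff = n_eff, exploded = exploded,
                 S = if (exploded) path$explosion_time else NA_real_),
            class = "wf_functionals")
}

## logical vector over grid intervals [k, k+1]: TRUE while both endpoints are
## strictly interior, truncated at the first failure and (when the path
## carries an explosion record, e.g. a thinned path whose clipped state was
## not stored) at the recorded explosion time.
usable_intervals <- function(path) {
  X <- path$X
  n <- nrow(X)
  interior <- rowSums(X <= 0) == 0
  ok <- interior[-n] & interior[-1]
  if (isTRUE(path$exploded) && is.finite(path$explosion_time))
    ok <- ok & (path$times[-1] < path$explosion_time - path$dt / 2)
  if (any(!ok)) ok[seq_along(ok) >= which.max(!ok)] <- FALSE
  ok
}

#' @export
print.wf_functionals <- function(x, ...) {
  cat("Path likelihood functionals: Y =", format(x$Y),
      ", I_T =", format(x$I), ", T_eff =", format(x$T_eff),
      if (x$exploded) "(exploded)" else "", "\n")
  invisible(x)
}

## pick streamed (full-resolution) functionals when present, else recompute
get_functionals <- function(path, model, use_streamed = TRUE) {
  if (use_streamed && !is.null(path$functionals)) {
    f <- path$functionals
    list(Y = f$Y, I = f$I, T_eff = f$T_eff, exploded = path$exploded,
         S = path$explosion_time)
  } else {
    f <- path_functionals(path, model)
    list(Y = f$Y, I = f$I, T_eff = f$T_eff, exploded = f$exploded, S = f$S)
  }
}

#' Maximum likelihood estimation of the recombination rate from a diffusion path
#'
#' Fits the recombination rate \eqn{\rho} of a Wright--Fisher diffusion from
#' an observed (gridded) haplotype-frequency trajectory.  The raw estimator
#' is the ratio of the score integral to the observed information,
#' \deqn{\hat\rho = \frac{\int_0^T \sum_{ij} (X_{i\cdot}X_{\cdot j}/X_{ij})\,
#'   d\tilde X_{ij}}{\int_0^T \sum_{ij} (X_{ij}-X_{i\cdot}X_{\cdot j})^2 /
#'   X_{ij}\, dt},}
#' and the reported estimate is the boundary-corrected MLE: on paths whose
#' information stays finite, \eqn{\max\{0, \hat\rho_T\}} (the parameter space
#' is \eqn{[0,\infty)}); on paths whose information explodes at the stopping
#' time \eqn{S \le T}, the running estimator's limit as \eqn{t \uparrow S},
#' which equals the true rate with probability 1.
#'
#' Two conventions are offered for exploded paths.  \code{"limit_at_S"}
#' (default) evaluates the raw estimator on the pre-explosion grid and
#' rectifies it to \eqn{[0,\infty)} --- the honest out-of-sample choice,
#' since discretization noise can leave the discrete limit slightly off the
#' (exactly learned) true value.  \code{"truth_assigned"} records the
#' model's true rate as the zero-error value; it is exact in continuous time
#' and is the convention used by the simulation-study harness, but it
#' presumes the generating rate is known, so it is only meaningful for
#' simulation experiments.
#'
#' For models with three or more loci the fit is the joint vector estimator
#' \eqn{\hat\varrho = I_T^{-1} Y} over the \eqn{\ell-1} interval rates
#' (componentwise rectified), or the single shared-rate estimator when
#' \code{shared_rate = TRUE}.
#'
#' @param path a \code{"wf_path"} from [simulate.wf_model()] or
#'   [read_path_csv()].
#' @param model the assumed model (compensator drift and, for
#'   \code{"truth_assigned"}, the true rate); defaults to the model stored
#'   with the path.
#' @param convention valuation of exploded paths (see Details).
#' @param use_streamed use the full-resolution functionals accumulated during
#'   simulation when available (recommended); otherwise recompute from the
#'   stored grid.
#' @param shared_rate multi-locus only: estimate a single common rate.
#' @return an object of class \code{"rho_mle"} with components
#'   \code{estimate}, \code{raw}, \code{I_T}, \code{Y}, \code{T_eff},
#'   \code{exploded}, \code{S}, \code{convention}.
#' @examples
#' m <- wf_model(rho = 5, theta_A = 5, theta_B = 5)
#' p <- simulate(m, seed = 7, dt = 1e-4)
#' fit <- rho_mle(p)
#' fit
#' coef(fit)
#' @export
rho_mle <- function(path, model = path$model,
                    convention = c("limit_at_S", "truth_assigned"),
                    use_streamed = TRUE, shared_rate = FALSE) {
  convention <- match.arg(convention)
  stopifnot(inherits(path, "wf_path"), inherits(model, "wf_model"))
  if (model$num_loci > 2L)
    return(rho_mle_multilocus(path, model, convention, use_streamed,
                              shared_rate))
  fn <- get_functionals(path, model, use_streamed)
  if (!is.finite(fn$I) || fn$I <= 0)
    stop("estimator undefined: the path carries no information about ",
         "recombination (I_T = 0; path at linkage equilibrium)")
  raw <- fn$Y / fn$I
  exploded <- isTRUE(fn$exploded)
  estimate <- if (exploded && convention == "truth_assigned") {
    model$rho
  } else {
    max(0, raw)
  }
  structure(list(estimate = estimate, raw = raw,
                 I_T = fn$I, Y = fn$Y, T_eff = fn$T_eff,
                 exploded = exploded, S = fn$S,
                 convention = if (exploded) convention else "finite_information",
                 model = model),
            class = "rho_mle")
}

rho_mle_multilocus <- function(path, model, convention, use_streamed,
                               shared_rate) {
  if (use_streamed && !is.null(path$functionals) &&
      is.matrix(path$functionals$I)) {
    Y <- path$functionals$Y
    I <- path$functionals$I
    T_eff <- path$functionals$T_eff
    exploded <- path$exploded
    S <- path$explosion_time
  } else {
    g <- generic_linear_mle(path, Z = function(x) {
      vapply(seq_len(model$num_loci - 1L), function(j) {
        mm <- multilocus_marginals(x, model$allele_counts, j)
        mm$prefix * mm$suffix - x
      }, numeric(model$d))
    }, c_fun = NULL, rectify = FALSE)
    Y <- g$Y; I <- g$I; T_eff <- g$T_eff; exploded <- g$exploded; S <- g$S
  }
  if (shared_rate) {
    Itot <- sum(I)
    if (Itot <= 0) stop("estimator undefined: I_T = 0")
    raw <- sum(Y) / Itot
    estimate <- if (exploded && convention == "truth_assigned")
      unique(model$rho)[1] else max(0, raw)
    I_rep <- Itot
  } else {
    if (rcond_psd(I) < 1e-14)
      stop("singular information matrix; deficient direction: ",
           paste(format(eigen(I, symmetric = TRUE)$vectors[, nrow(I)],
                        digits = 3), collapse = ", "))
    raw <- as.vector(solve(I, Y))
    estimate <- if (exploded && convention == "truth_assigned")
      model$rho else pmax(0, raw)
    I_rep <- I
  }
  structure(list(estimate = estimate, raw = raw, I_T = I_rep, Y = Y,
                 T_eff = T_eff, exploded = exploded, S = S,
                 convention = if (exploded) convention else "finite_information",
                 model = model),
            class = "rho_mle")
}

rcond_psd <- function(I) {
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

#' @export
print.rho_mle <- function(x, ...) {
  lab <- if (length(x$estimate) > 1) "rates" else "rate"
  cat("Recombination-", lab, " MLE (corrected): ",
      paste(format(x$estimate), collapse = ", "), "\n", sep = "")
  cat("  raw estimator:", paste(format(x$raw), collapse = ", "), "\n")
  if (x$exploded)
    cat("  information exploded at S =", format(x$S),
        "; convention:", x$convention, "\n")
  else
    cat("  I_T =", paste(format(x$I_T), collapse = ", "),
        "over T_eff =", format(x$T_eff), "\n")
  invisible(x)
}

#' @export
coef.rho_mle <- function(object, ...) object$estimate

#' @export
vcov.rho_mle <- function(object, ...) {
  if (object$exploded) {
    matrix(0, length(object$estimate), length(object$estimate))
  } else if (is.matrix(object$I_T)) solve(object$I_T)
  else matrix(1 / object$I_T, 1, 1)
}

#' @export
logLik.rho_mle <- function(object, ...) {
  ## quasi-log-likelihood relative to the rho_0 = 0 reference measure
  est <- object$estimate
  val <- if (is.matrix(object$I_T))
    sum(est * object$Y) - 0.5 * drop(t(est) %*% object$I_T %*% est)
  else sum(est * object$Y) - 0.5 * sum(est^2) * object$I_T
  structure(val, df = length(est), class = "logLik")
}

#' @export
summary.rho_mle <- function(object, ...) {
  se <- if (object$exploded) 0 else sqrt(diag(vcov(object)))
  out <- list(fit = object, se = se)
  class(out) <- "summary.rho_mle"
  out
}

#' @export
print.summary.rho_mle <- function(x, ...) {
  print(x$fit)
  if (!x$fit$exploded)
    cat("  curvature-based standard error:",
        paste(format(x$se), collapse = ", "),
        "(quasi-likelihood; explosion regime excluded)\n")
  else
    cat("  parameter learned without error at S (zero standard error)\n")
  invisible(x)
}

#' @export
plot.rho_mle <- function(x, ...) {
  if (length(x$estimate) > 1 || x$exploded) {
    stop("log-likelihood curve plot available for finite-information ",
         "scalar fits only")
  }
  r <- x$estimate + c(-1, 1) * 3 / sqrt(x$I_T)
  rr <- seq(max(0, r[1]), max(r[2], 1e-6), length.out = 200)
  ll <- rr * x$Y - 0.5 * rr^2 * x$I_T
  plot(rr, ll, type = "l", xlab = expression(rho),
       ylab = "quasi-log-likelihood", ...)
  abline(v = x$estimate, lty = 3)
  invisible(x)
}

#' Generic linear-drift maximum likelihood estimator
#'
#' Estimates any parameter vector entering the drift linearly,
#' \eqn{a_i(x;\varphi) = \sum_k Z_{ik}(x)\varphi_k}, from a stored path:
#' solves \eqn{I_T \hat\varphi = Y} with
#' \eqn{Y_k = \int \sum_i Z_{ik}/X_i\, d\tilde X_i} and
#' \eqn{I_{kl} = \int \sum_i Z_{ik} Z_{il}/X_i\, dt}.  With the
#' recombination score \eqn{Z = x_{i\cdot}x_{\cdot j} - x_{ij}} this
#' reproduces [rho_mle()]'s raw estimator exactly.
#'
#' @param path a \code{"wf_path"}.
#' @param Z function mapping a state vector to its \eqn{d \times r} score
#'   matrix (columns linearly independent).
#' @param c_fun optional compensator drift function of the state (defaults
#'   to no compensation, \eqn{c \equiv 0}).
#' @param rectify componentwise rectification \eqn{\max\{0,\cdot\}} of the
#'   solution (appropriate for rate parameters on \eqn{[0,\infty)}).
#' @return list with \code{estimate}, \code{raw}, \code{Y} (length r),
#'   \code{I} (\eqn{r \times r}), \code{T_eff}, \code{exploded}, \code{S}.
#' @export
generic_linear_mle <- function(path, Z, c_fun = NULL, rectify = FALSE) {
  stopifnot(inherits(path, "wf_path"))
  X <- path$X
  n <- nrow(X)
  dts <- diff(path$times)
  lef <- which(usable_intervals(path))
  if (length(lef) == 0) stop("no interior grid interval before the explosion")
  r <- ncol(as.matrix(Z(X[1, ])))
  Y <- numeric(r)
  I <- matrix(0, r, r)
  for (k in lef) {
    x <- X[k, ]
    Zk <- as.matrix(Z(x))
    h <- dts[k]
    comp <- if (is.null(c_fun)) 0 else c_fun(x) * h
    dxt <- (X[k + 1L, ] - x) - comp
    Y <- Y + as.vector(crossprod(Zk / x, dxt))
    I <- I + crossprod(Zk / sqrt(x)) * h
  }
  if (rcond_psd(I) < 1e-14) {
    v <- eigen(I, symmetric = TRUE)$vectors[, r]
    stop("singular information matrix; deficient direction: ",
         paste(format(v, digits = 3), collapse = ", "))
  }
  raw <- as.vector(solve(I, Y))
  exploded <- isTRUE(path$exploded) || length(lef) < n - 1L
  list(estimate = if (rectify) pmax(0, raw) else raw,
       raw = raw, Y = Y, I = I, T_eff = sum(dts[lef]),
       exploded = exploded,
       S = if (exploded) path$explosion_time else NA_real_)
}

#' Genic selection estimator at one allele
#'
#' The MLE of the genic selection coefficient \eqn{s^A_k} for allele \eqn{k}
#' at locus A from an observed path,
#' \deqn{\hat s^A_k = \frac{2(\tilde X_{k\cdot}(T) - \tilde X_{k\cdot}(0))}
#'   {\int_0^T X_{k\cdot}(t)(1 - X_{k\cdot}(t))\,dt},}
#' with the locus-A marginal compensated by the mutation drift.  With both
#' mutation rates zero this is the classical selection estimator from a
#' diallelic drift-and-selection path.  It coincides with the selection
#' component of the joint \eqn{(\rho, s^A_k)} fit because the joint observed
#' information is diagonal.
#'
#' @param path a \code{"wf_path"}.
#' @param model the assumed model (mutation compensator).
#' @param k allele index at locus A.
#' @param use_streamed use functionals accumulated during simulation when the
#'   path was simulated with \code{joint_selection_allele = k}.
#' @return list with \code{estimate}, \code{Y}, \code{I} (scalars).
#' @export
selection_estimator <- function(path, model = path$model, k = 1,
                                use_streamed = TRUE) {
  stopifnot(inherits(path, "wf_path"), model$num_loci == 2L)
  f <- path$functionals
  if (use_streamed && !is.null(f) && f$I_sel > 0) {
    if (f$I_sel <= 0) stop("zero selection information")
    return(list(estimate = f$Y_sel / f$I_sel, Y = f$Y_sel, I = f$I_sel))
  }
  X <- path$X
  dts <- diff(path$times)
  lef <- which(usable_intervals(path))
  cols <- ((k - 1L) * model$L + 1L):(k * model$L)
  XL <- X[lef, , drop = FALSE]
  xk <- rowSums(XL[, cols, drop = FALSE])
  h <- dts[lef]
  I <- 0.25 * sum(xk * (1 - xk) * h)
  if (I <= 0) stop("zero selection information: marginal constant at 0 or 1")
  C <- XL %*% t(mutation_generator(model))
  dXt <- (X[lef + 1L, , drop = FALSE] - XL) - C * h
  Y <- 0.5 * sum(dXt[, cols, drop = FALSE])
  list(estimate = Y / I, Y = Y, I = I)
}

#' Exact error decomposition of the raw estimator
#'
#' On a simulated path with stored Brownian increments, the estimation error
#' decomposes as \eqn{\hat\rho - \rho = -N_T / I_T} where
#' \eqn{N_T = \int \sum_i (D_i/X_i) \sum_j \sigma_{ij}\,dW_j} is a
#' martingale whose quadratic variation equals the accumulated information.
#' This identity holds step-by-step in the Euler--Maruyama scheme (up to the
#' compensator's left-point rounding), so the predicted error matches the
#' realized one to discretization accuracy; it is the engine behind the
#' exact learning of \eqn{\rho} upon explosion.
#'
#' @param path a \code{"wf_path"} simulated with
#'   \code{store_increments = TRUE} (the streamed martingale is always
#'   available; the discrete quadratic variation additionally needs a full
#'   resolution stored path).
#' @param model the assumed model.
#' @param true_rho the generating rate (defaults to the model's).
#' @return list with \code{N} (martingale at \eqn{T \wedge S}),
#'   \code{predicted_error} (\eqn{-N/I_T}), \code{observed_error}
#'   (\eqn{\hat\rho - \rho}), \code{I} and, when computable, \code{qv}
#'   (discrete quadratic variation of \eqn{N}).
#' @export
error_decomposition <- function(path, model = path$model,
                                true_rho = model$rho) {
  stopifnot(inherits(path, "wf_path"))
  f <- path$functionals
  if (is.null(f) || is.na(f$N))
    stop("error decomposition needs a simulated path (streamed martingale)")
  ## N is stored as the (already negated) error martingale
  ## -int sum_i (D_i/X_i) (sigma dW)_i, so the predicted error is N/I
  pred <- f$N / f$I
  obs <- f$Y / f$I - true_rho
  qv <- NA_real_
  if (!is.null(path$dW) && nrow(path$X) == nrow(path$dW) + 1L) {
    X <- path$X
    n_eff <- f$n_eff
    qv <- 0
    for (kk in seq_len(n_eff)) {
      x <- X[kk, ]
      Dv <- linkage_disequilibrium(x, model$K, model$L)
      noise <- as.vector(sigma_pal(x) %*% path$dW[kk, ])
      qv <- qv + sum(Dv / x * noise)^2
    }
  }
  list(N = f$N, predicted_error = pred, observed_error = obs,
       I = f$I, qv = qv)
}

#' Replay a path from its stored Brownian increments
#'
#' Re-applies the Euler--Maruyama update rule from the initial state using
#' the stored increments; used to verify that a stored path is exactly
#' reproducible from its noise realization.
#'
#' @param path a full-resolution \code{"wf_path"} with stored increments.
#' @return matrix of replayed states, same shape as \code{path$X}.
#' @export
replay_path <- function(path) {
  stopifnot(!is.null(path$dW), nrow(path$X) == nrow(path$dW) + 1L)
  model <- path$model
  X <- matrix(NA_real_, nrow(path$X), ncol(path$X))
  x <- path$X[1, ]
  X[1, ] <- x
  dt <- path$dt
  for (k in seq_len(nrow(path$dW))) {
    mu <- drift_total(x, model)
    xnew <- x + mu * dt + as.vector(sigma_pal(x) %*% path$dW[k, ])
    xnew[xnew <= 0] <- 0
    xnew <- xnew / sum(xnew)
    x <- xnew
    X[k + 1L, ] <- x
  }
  X
}
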