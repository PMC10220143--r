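## Replication harness for the simulation study: a grid of mutation and
## recombination settings for the diallelic two-locus model with symmetric
## parent-independent mutation, initial state (2/5, 1/5, 1/5, 1/5),
## dt = 1e-6, horizon T = 1 and 100 replicates per cell.

#' Default simulation-study design
#'
#' The study conditions: diallelic two-locus model, symmetric mutation
#' transition matrices (all entries 1/2), initial haplotype frequencies
#' \code{c(2/5, 1/5, 1/5, 1/5)}, stepsize \code{1e-6}, horizon 1, mutation
#' rates \eqn{\theta_A = \theta_B \in \{1, 5\}}, recombination rates
#' \eqn{\rho \in \{0, 0.1, 1, 2.5, 5, 10, 25\}}, 100 replicates per cell,
#' exploded replicates valued at the generating rate (they learn it without
#' error).
#'
#' @return a list of study parameters accepted by [run_cell()] and
#'   [run_table1()].
#' @export
study_spec <- function() {
  list(thetas = c(5, 1),
       rhos = c(0, 0.1, 1, 2.5, 5, 10, 25),
       x0 = c(2, 1, 1, 1) / 5,
       dt = 1e-6, t_end = 1, n_replicates = 100,
       convention = "truth_assigned", level = 0.05)
}

#' Run one cell of the simulation study
#'
#' Simulates \code{n_replicates} paths at the given mutation and
#' recombination rates, fits the corrected MLE to each, tests
#' \eqn{\rho_0 = 0}, and summarizes: mean, variance, 5th/50th/95th
#' percentiles (linear-interpolation convention), frequency of zero error
#' (the information-explosion event, on which the rate is learned exactly),
#' and empirical power at the stated
#' level.  Replicate \code{r} of cell \code{(theta, rho)} draws its seed
#' substream from \code{(seed, theta-index, rho-index, r)} so every cell is
#' independently reproducible.
#'
#' @param theta common mutation rate \eqn{\theta_A = \theta_B}.
#' @param rho generating recombination rate.
#' @param n_replicates replicates (default 100).
#' @param dt stepsize (default \code{1e-6}; coarser grids speed exploratory
#'   runs at the cost of extra boundary-clipping at high mutation rates).
#' @param t_end horizon.
#' @param seed master seed.
#' @param convention exploded-replicate valuation, see [rho_mle()].
#' @param level test size.
#' @param x0 initial state.
#' @param cell_id integer pair identifying the cell in the seed derivation
#'   (defaults to a hash of \code{theta} and \code{rho}).
#' @return list with \code{summary} (one-row data.frame) and
#'   \code{replicates} (per-replicate data.frame: raw, estimate, exploded,
#'   S, I_T, lambda, reject).
#' @export
run_cell <- function(theta, rho, n_replicates = 100, dt = 1e-6, t_end = 1,
                     seed = 1, convention = "truth_assigned", level = 0.05,
                     x0 = c(2, 1, 1, 1) / 5, cell_id = NULL) {
  model <- wf_model(rho = rho, theta_A = theta, theta_B = theta)
  if (is.null(cell_id)) cell_id <- c(round(1e3 * theta), round(1e3 * rho))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p <- simulate(model, seed = derive_seed(seed, cell_id[1], cell_id[2], r),
                  x0 = x0, dt = dt, t_end = t_end, store_path = FALSE)
    fit <- rho_mle(p, convention = convention)
    tst <- lrt_recombination(fit, level = level)
    rows[[r]] <- data.frame(
      replicate = r, raw = fit$raw, estimate = fit$estimate,
      exploded = fit$exploded, S = if (fit$exploded) fit$S else NA_real_,
      I_T = fit$I_T, T_eff = fit$T_eff,
      lambda = tst$lambda, reject = tst$reject)
  }
  reps <- do.call(rbind, rows)
  est <- reps$estimate
  qs <- stats::quantile(est, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  summary <- data.frame(
    theta = theta, rho_true = rho,
    mean = mean(est), variance = stats::var(est),
    pct5 = qs[1], median = qs[2], pct95 = qs[3],
    freq_zero_error = mean(reps$exploded),
    power = mean(reps$reject),
    n_exploded = sum(reps$exploded))
  list(summary = summary, replicates = reps)
}

#' Run the full simulation-study grid
#'
#' All \eqn{(\theta, \rho)} cells of [study_spec()] (14 by default), each
#' summarized as in [run_cell()].  Explosion counts are reported per cell so
#' the sensitivity of the clipping frequency to the stepsize stays visible.
#'
#' @param spec a study design from [study_spec()] (fields may be
#'   overridden).
#' @param seed master seed.
#' @param dt optional stepsize override for scaled-down runs.
#' @param n_replicates optional replicate-count override.
#' @param verbose print one line per finished cell.
#' @return data.frame with one row per cell (the \code{summary} rows of
#'   [run_cell()]); per-replicate tables are attached as the
#'   \code{"replicates"} attribute (a named list).
#' @export
run_table1 <- function(spec = study_spec(), seed = 1, dt = NULL,
                       n_replicates = NULL, verbose = FALSE) {
  if (!is.null(dt)) spec$dt <- dt
  if (!is.null(n_replicates)) spec$n_replicates <- n_replicates
  out <- list(); reps <- list()
  for (theta in spec$thetas) {
    for (rho in spec$rhos) {
      t0 <- proc.time()[["elapsed"]]
      cell <- run_cell(theta, rho, n_replicates = spec$n_replicates,
                       dt = spec$dt, t_end = spec$t_end, seed = seed,
                       convention = spec$convention, level = spec$level,
                       x0 = spec$x0)
      key <- sprintf("theta%g_rho%g", theta, rho)
      out[[key]] <- cell$summary
      reps[[key]] <- cell$replicates
      if (verbose)
        message(sprintf(
          "cell theta=%g rho=%g: mean=%.2f P(zero error)=%.2f power=%.2f (%d exploded, %.1fs)",
          theta, rho, cell$summary$mean, cell$summary$freq_zero_error,
          cell$summary$power, cell$summary$n_exploded,
          proc.time()[["elapsed"]] - t0))
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "replicates") <- reps
  tab
}

#' Single-path diagnostics: running estimator and information
#'
#' Simulates one replicate with a thinned stored path and returns the time
#' series of the running corrected estimator and the running information
#' (monotone by construction), as plotted alongside individual trajectories.
#' On a path whose information explodes the running error
#' \eqn{\hat\rho_{MLE}(t) - \rho} is truncated at \eqn{S}, where it has
#' converged to 0.
#'
#' @param theta,rho cell parameters.
#' @param seed seed.
#' @param dt,t_end grid.
#' @param thin storage stride for the diagnostic series (default 1000).
#' @param x0 initial state.
#' @return list with \code{path} (the \code{"wf_path"}) and
#'   \code{series}: data.frame of \code{time}, running \code{rho_hat}
#'   (rectified running estimator, NA where no information has accrued yet),
#'   running \code{information}, and running \code{error}.
#' @export
run_path_diagnostics <- function(theta, rho, seed = 1, dt = 1e-6, t_end = 1,
                                 thin = 1000, x0 = c(2, 1, 1, 1) / 5) {
  model <- wf_model(rho = rho, theta_A = theta, theta_B = theta)
  p <- simulate(model, seed = seed, x0 = x0, dt = dt, t_end = t_end,
                thin = thin, store_path = TRUE)
  run <- p$run
  keep <- if (p$exploded) run$times < p$explosion_time else rep(TRUE, length(run$times))
  rh <- ifelse(run$I[keep] > 0, pmax(0, run$Y[keep] / run$I[keep]), NA_real_)
  series <- data.frame(time = run$times[keep],
                       rho_hat = rh,
                       information = run$I[keep],
                       error = rh - rho)
  if (p$exploded) {
    ## at S the rate is learned without error and the information is infinite
    series <- rbind(series,
                    data.frame(time = p$explosion_time, rho_hat = rho,
                               information = Inf, error = 0))
  }
  list(path = p, series = series)
}
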