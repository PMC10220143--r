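#' Simulate Wright--Fisher diffusion paths
#'
#' Euler--Maruyama simulation of the haplotype-frequency SDE
#' \deqn{dX(t) = [c(X(t)) + a(X(t);\rho)]\,dt + \sigma(X(t))\,dW(t)}
#' on a uniform grid of stepsize \code{dt} up to time \code{t_end}, using the
#' bounded symmetric square root \eqn{\sigma} of [sigma_pal()] (so the noise
#' is driven by \eqn{d} Brownian coordinates).  If a proposed coordinate
#' falls to or below 0 it is clipped to 0, the state renormalized to the
#' simplex, and the event recorded as an \emph{explosion} of the observed
#' information (the first such time is the stopping time \eqn{S}); simulation
#' continues to \code{t_end} but the likelihood functionals are only
#' accumulated over the pre-explosion segment, at full step resolution
#' regardless of the storage thinning.
#'
#' Two-locus models (with mutation and optional selection) run in compiled
#' code; models with three or more loci (recombination only) use a plain R
#' stepper and are intended for short illustrative grids.
#'
#' @param object a \code{"wf_model"}.
#' @param nsim number of replicate paths.
#' @param seed integer seed; replicate \code{r} uses an independent
#'   reproducible substream derived from \code{(seed, r)} (see
#'   [derive_seed()]).
#' @param x0 initial frequencies, strictly interior.  Default for the
#'   diallelic two-locus model: \code{c(2/5, 1/5, 1/5, 1/5)}; otherwise
#'   uniform.
#' @param dt timestep (default \code{1e-6}).
#' @param t_end time horizon (default 1).
#' @param thin store every \code{thin}-th state (default: about 1000 stored
#'   rows).  Thinning affects storage only, never the accumulated integrals.
#' @param store_path keep the (thinned) trajectory; set \code{FALSE} for
#'   large replicate batches where only the functionals are needed (first and
#'   last states are always kept).
#' @param store_increments store the Brownian increments (full resolution;
#'   memory-heavy, intended for short paths and the error-decomposition
#'   identity).
#' @param zero_noise replace the Brownian increments by 0 (deterministic
#'   drift-only stepping; used for sanity checks against the closed-form
#'   dynamics).
#' @param joint_selection_allele optional allele index \eqn{k} at locus A:
#'   additionally accumulate the score/information functionals for joint
#'   estimation of \eqn{(\rho, s^A_k)} (compensated by mutation only).
#' @param selection_known if the model carries selection, whether it belongs
#'   to the known compensator \eqn{c} (\code{TRUE}, the confounder case) or
#'   is excluded from it (\code{FALSE}, the joint-estimation case).
#' @param ... unused.
#' @return a \code{"wf_path"} for \code{nsim = 1}, else a list of them.
#' @examples
#' m <- wf_model(rho = 1, theta_A = 1, theta_B = 1)
#' p <- simulate(m, seed = 1, dt = 1e-4)
#' p
#' @export
simulate.wf_model <- function(object, nsim = 1, seed = NULL,
                              x0 = NULL, dt = 1e-6, t_end = 1,
                              thin = NULL, store_path = TRUE,
                              store_increments = FALSE, zero_noise = FALSE,
                              joint_selection_allele = NULL,
                              selection_known = TRUE, ...) {
  model <- object
  if (is.null(x0)) {
    x0 <- if (model$d == 4L && model$num_loci == 2L)
      c(2, 1, 1, 1) / 5 else rep(1 / model$d, model$d)
  }
  check_freq(x0, model$d, interior = TRUE)
  if (dt <= 0 || dt >= t_end) stop("need 0 < dt < t_end")
  nsteps <- round(t_end / dt)
  if (is.null(thin)) thin <- if (store_path) max(1L, nsteps %/% 1000L) else nsteps
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)

  one <- function(r) {
    set.seed(derive_seed(seed, r))
    if (model$num_loci == 2L) {
      raw <- sim_wf_cpp(
        x0, model$K, model$L,
        mutation_generator(model),
        has_mut = model$theta_A > 0 || model$theta_B > 0,
        Smat = if (is.null(model$selection)) matrix(0, 1, 1)
               else selection_tensor(model$selection, model$K, model$L),
        has_sel = !is.null(model$selection),
        sel_in_c = isTRUE(selection_known),
        rho = model$rho, dt = dt, nsteps = nsteps, thin = thin,
        store_path = store_path, store_dw = store_increments,
        zero_noise = zero_noise,
        sel_k = if (is.null(joint_selection_allele)) 0L
                else as.integer(joint_selection_allele))
    } else {
      raw <- sim_wf_r(model, x0, dt, nsteps, thin, store_path,
                      store_increments, zero_noise)
    }
    as_wf_path(raw, model, dt, t_end, seed_used = derive_seed(seed, r))
  }
  paths <- lapply(seq_len(nsim), one)
  if (nsim == 1) paths[[1]] else paths
}

## plain-R stepper for >= 3 loci (recombination drift only)
sim_wf_r <- function(model, x0, dt, nsteps, thin, store_path,
                     store_dw, zero_noise) {
  d <- model$d
  x <- x0
  sdt <- sqrt(dt)
  keep <- if (store_path) unique(c(0L, seq_len(nsteps)[seq_len(nsteps) %% thin == 0L], nsteps))
          else c(0L, nsteps)
  X <- matrix(NA_real_, length(keep), d)
  runY <- runI <- numeric(length(keep))
  dW <- if (store_dw) matrix(NA_real_, nsteps, d) else NULL
  row <- 1L
  X[row, ] <- x
  ell <- model$num_loci
  r <- ell - 1L
  Y <- numeric(r); I <- matrix(0, r, r)
  exploded <- FALSE; explosion_step <- 0L; n_eff <- 0L
  for (step in seq_len(nsteps)) {
    Z <- vapply(seq_len(r), function(j) {
      mm <- multilocus_marginals(x, model$allele_counts, j)
      mm$prefix * mm$suffix - x
    }, numeric(d))                      # d x r score matrix
    a <- as.vector(Z %*% model$rho)
    if (zero_noise) {
      noise <- numeric(d)
    } else {
      dw <- sdt * stats::rnorm(d)
      if (store_dw) dW[step, ] <- dw
      sx <- sqrt(x)
      noise <- sx * dw - x * sum(sx * dw)
    }
    xnew <- x + a * dt + noise
    clipped <- any(xnew <= 0)
    xnew[xnew <= 0] <- 0
    xnew <- xnew / sum(xnew)
    if (clipped && !exploded) { exploded <- TRUE; explosion_step <- step }
    if (!exploded) {
      dxt <- xnew - x                   # c = 0 beyond two loci
      Y <- Y + as.vector(t(Z / x) %*% dxt)
      I <- I + crossprod(Z / sqrt(x)) * dt
      n_eff <- n_eff + 1L
    }
    x <- xnew
    if (step %in% keep) {
      row <- row + 1L
      X[row, ] <- x
      runY[row] <- Y[1]; runI[row] <- I[1, 1]
    }
  }
  list(X = X[seq_len(row), , drop = FALSE], step_idx = keep[seq_len(row)],
       Y = Y, Yd = Y, I1 = I, I2raw = NULL, N = NA_real_,
       Ysel = 0, Isel = 0, Icross = 0, n_eff = as.double(n_eff),
       exploded = exploded, explosion_step = explosion_step,
       run_Y = runY[seq_len(row)], run_I = runI[seq_len(row)],
       dW = dW)
}

as_wf_path <- function(raw, model, dt, t_end, seed_used) {
  es <- raw$explosion_step
  structure(
    list(times = raw$step_idx * dt,
         X = raw$X,
         dW = raw$dW,
         dt = dt, t_end = t_end, model = model, seed = seed_used,
         exploded = isTRUE(raw$exploded),
         explosion_step = if (isTRUE(raw$exploded)) es else NA_integer_,
         explosion_time = if (isTRUE(raw$exploded)) es * dt else NA_real_,
         functionals = list(
           Y = raw$Y, Y_ld_form = raw$Yd,
           I = raw$I1,
           I_expanded = if (!is.null(raw$I2raw)) raw$I2raw - raw$n_eff * dt,
           N = raw$N,
           Y_sel = raw$Ysel, I_sel = raw$Isel, I_cross = raw$Icross,
           n_eff = raw$n_eff, T_eff = raw$n_eff * dt),
         run = list(times = raw$step_idx * dt, Y = raw$run_Y, I = raw$run_I)),
    class = "wf_path")
}

#' @export
print.wf_path <- function(x, ...) {
  cat("Wright-Fisher diffusion path (Euler-Maruyama, dt =", format(x$dt),
      ", T =", format(x$t_end), ")\n")
  cat("  d =", ncol(x$X), "haplotypes;", nrow(x$X), "stored states\n")
  if (x$exploded)
    cat("  information exploded at S =", format(x$explosion_time),
        "(functionals accumulated on [0, S))\n")
  else
    cat("  no explosion: information finite on [0, T]\n")
  invisible(x)
}

#' @export
plot.wf_path <- function(x, ...) {
  matplot(x$times, x$X, type = "l", lty = 1,
          xlab = "time", ylab = "haplotype frequency", ...)
  if (x$exploded) abline(v = x$explosion_time, lty = 3)
  invisible(x)
}

#' Simulate a batch of replicate paths
#'
#' Convenience wrapper over [simulate.wf_model()] with per-replicate seed
#' substreams; replicate \code{r} is reproducible in isolation from
#' \code{(seed, r)}.
#'
#' @param model a \code{"wf_model"}.
#' @param n_replicates number of paths.
#' @param seed master seed.
#' @param ... passed to [simulate.wf_model()].
#' @return list of \code{"wf_path"} objects.
#' @export
batch_simulate <- function(model, n_replicates, seed = NULL, ...) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  out <- simulate(model, nsim = n_replicates, seed = seed, ...)
  if (n_replicates == 1) list(out) else out
}

#' Reproducible seed substreams
#'
#' Derives a 31-bit seed from a master seed and one or more stream indices by
#' iterating a multiplicative-congruential mix, so that experiment cells and
#' replicates are independently reproducible and parallelizable.
#'
#' @param master integer master seed.
#' @param ... integer stream indices (e.g. cell index, replicate number).
#' @return a single integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(master, ...) {
  mod <- 2147483629          # prime below 2^31; products stay under 2^53
  h <- as.double(master) %% mod
  for (k in c(...)) h <- (h * 69069 + as.double(k) + 1) %% mod
  as.integer(h %% (2^31 - 3) + 1)
}

## ---- trajectory file I/O --------------------------------------------------

#' Write / read a trajectory as CSV
#'
#' Plain tabular format: a \code{time} column then one column per haplotype
#' frequency, named \code{x_<i><j>} for two-locus models (\code{x_11, x_12,
#' ...}) or \code{x_<flatindex>} otherwise, at full float precision
#' (round-trip lossless).  A YAML sidecar (\code{<path>.meta.yaml}) records
#' the model parameters, seed, stepsize and explosion time.
#'
#' @param path a \code{"wf_path"}.
#' @param file output CSV path.
#' @return \code{write_path_csv} returns \code{file} invisibly;
#'   \code{read_path_csv} returns a \code{"wf_path"} (with functionals
#'   recomputed lazily by the estimators at the stored resolution).
#' @export
write_path_csv <- function(path, file) {
  stopifnot(inherits(path, "wf_path"))
  model <- path$model
  if (model$num_loci == 2L) {
    nm <- paste0("x_", rep(seq_len(model$K), each = model$L),
                 rep(seq_len(model$L), times = model$K))
  } else nm <- paste0("x_", seq_len(model$d))
  df <- data.frame(time = path$times, path$X)
  names(df) <- c("time", nm)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     file, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- list(dt = path$dt, t_end = path$t_end, seed = path$seed,
               exploded = path$exploded,
               explosion_time = if (path$exploded) path$explosion_time else NULL)
  yaml::write_yaml(meta, paste0(file, ".meta.yaml"), precision = 17L)
  write_wf_model(model, paste0(file, ".model.yaml"))
  invisible(file)
}

#' @rdname write_path_csv
#' @export
read_path_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  meta_f <- paste0(file, ".meta.yaml")
  model_f <- paste0(file, ".model.yaml")
  meta <- if (file.exists(meta_f)) yaml::read_yaml(meta_f) else list()
  model <- if (file.exists(model_f)) read_wf_model(model_f) else NULL
  X <- as.matrix(df[, -1, drop = FALSE])
  dimnames(X) <- NULL
  times <- df$time
  dt <- meta$dt %||% stats::median(diff(times))
  exploded <- isTRUE(meta$exploded)
  structure(
    list(times = times, X = X, dW = NULL,
         dt = dt, t_end = meta$t_end %||% times[length(times)],
         model = model, seed = meta$seed,
         exploded = exploded,
         explosion_step = NA_integer_,
         explosion_time = if (exploded) meta$explosion_time else NA_real_,
         functionals = NULL, run = NULL),
    class = "wf_path")
}
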