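# score and information functionals, the raw and corrected estimators,
# generic linear-drift fits, selection and multi-locus estimators,
# and the exact error decomposition

make_const_path <- function(x, t_end = 1, dt = 1e-2, model = model_neutral()) {
  tt <- seq(0, t_end, by = dt)
  structure(list(times = tt, X = matrix(x, length(tt), length(x), byrow = TRUE),
                 dW = NULL, dt = dt, t_end = t_end, model = model,
                 seed = NA_integer_, exploded = FALSE,
                 explosion_step = NA_integer_, explosion_time = NA_real_,
                 functionals = NULL, run = NULL),
            class = "wf_path")
}

test_that("information of a constant path matches hand arithmetic", {
  # sum D^2/x = 0.0016/0.4 + 3 * 0.0016/0.2 = 0.028 over unit time
  p <- make_const_path(c(0.4, 0.2, 0.2, 0.2))
  fn <- path_functionals(p)
  expect_equal(fn$I, 0.028, tolerance = 1e-12)
  expect_equal(fn$I_expanded, fn$I, tolerance = 1e-10)
  expect_equal(fn$Y, 0)       # no increments
  # constant path at linkage equilibrium carries no information
  # (uniform state: D is exactly zero in floating point)
  peq <- make_const_path(rep(0.25, 4))
  expect_equal(path_functionals(peq)$I, 0, tolerance = 1e-14)
  expect_error(rho_mle(peq), "no information")
})

test_that("compensated increments follow their definition", {
  # constant path with nonzero mutation drift: dXtilde = -c(x) dt
  m <- model_sym(theta = 1)
  p <- make_const_path(c(0.4, 0.2, 0.2, 0.2), model = m, dt = 0.1)
  cvec <- drift_mutation(c(0.4, 0.2, 0.2, 0.2), m)
  # score integral Y = sum_steps sum_i (m_i/x_i) * (-c_i dt)
  mp <- marginal_product(c(0.4, 0.2, 0.2, 0.2), 2, 2)
  expected_Y <- 10 * sum(mp / c(0.4, 0.2, 0.2, 0.2) * (-cvec * 0.1))
  expect_equal(path_functionals(p)$Y, expected_Y, tolerance = 1e-12)
  # the two printed forms of the score agree on stochastic paths
  ps <- sim_full(model_sym(rho = 3, theta = 5), seed = 8, dt = 1e-3)
  fn <- path_functionals(ps)
  expect_equal(fn$Y, fn$Y_ld_form, tolerance = 1e-10)
  expect_equal(fn$I, fn$I_expanded, tolerance = 1e-8)
})

test_that("streamed functionals agree with grid recomputation", {
  m <- model_sym(rho = 2, theta = 5)
  p <- simulate(m, seed = 14, dt = 1e-3, t_end = 1, thin = 1)
  fn <- path_functionals(p)
  expect_equal(p$functionals$Y, fn$Y, tolerance = 1e-10)
  expect_equal(p$functionals$I, fn$I, tolerance = 1e-10)
  expect_equal(p$functionals$I_expanded, fn$I_expanded, tolerance = 1e-8)
  expect_equal(p$functionals$T_eff, fn$T_eff)
  # brute-force per-step loop oracle for Y on a short path
  X <- p$X; dts <- diff(p$times)
  Y <- 0
  for (k in seq_len(100)) {
    x <- X[k, ]
    D <- linkage_disequilibrium(x)
    dxt <- (X[k + 1, ] - x) - drift_mutation(x, m) * dts[k]
    Y <- Y - sum(D / x * dxt)
  }
  p100 <- p
  p100$X <- X[1:101, ]; p100$times <- p$times[1:101]
  p100$functionals <- NULL
  expect_equal(path_functionals(p100, m)$Y, Y, tolerance = 1e-12)
})

test_that("deterministic-path estimator recovers the true rate at O(dt)", {
  expect_equal(estimator_on_deterministic_path(x0_study, 0, 1, 1e-3), 0)
  e1 <- abs(estimator_on_deterministic_path(x0_study, 5, 1, 1e-3) - 5)
  e2 <- abs(estimator_on_deterministic_path(x0_study, 5, 1, 5e-4) - 5)
  e3 <- abs(estimator_on_deterministic_path(x0_study, 5, 1, 2.5e-4) - 5)
  expect_lt(abs(estimator_on_deterministic_path(x0_study, 5, 1, 1e-4) - 5),
            0.05)
  # slope-1 convergence in dt (log-log slope near 1)
  slope <- coef(lm(log(c(e1, e2, e3)) ~ log(c(1e-3, 5e-4, 2.5e-4))))[2]
  expect_equal(unname(slope), 1, tolerance = 0.15)
})

test_that("closed-form deterministic information matches quadrature", {
  # Riemann sum along the closed-form path vs the log formula
  p <- deterministic_path(x0_study, 5, 1, 1e-5)
  I_riemann <- path_functionals(p)$I
  expect_equal(I_riemann, info_closed_form(x0_study, 5, 1),
               tolerance = 1e-4)
  expect_equal(info_limit(x0_study, 5), 2.776e-3, tolerance = 1e-3)
  # increasing in T with a finite limit
  Ts <- c(0.25, 0.5, 1, 2, 5, Inf)
  Is <- vapply(Ts, function(T) info_closed_form(x0_study, 5, T), numeric(1))
  expect_true(all(diff(Is) > 0))
  expect_lt(Is[5], Is[6] + 1e-12)
  expect_equal(ode_solution(x0_study, 5, 0), x0_study)
  expect_equal(ode_solution(x0_study, 5, Inf), c(0.36, 0.24, 0.24, 0.16))
  # the closed form solves the flow: finite-difference derivative oracle
  h <- 1e-7
  dnum <- (ode_solution(x0_study, 5, 0.3 + h) -
             ode_solution(x0_study, 5, 0.3 - h)) / (2 * h)
  expect_equal(dnum, drift_recombination(ode_solution(x0_study, 5, 0.3), 5),
               tolerance = 1e-6)
})

test_that("deterministic mutation-recombination path has bounded information", {
  m <- model_sym(rho = 3, theta = 2)
  p <- deterministic_path_mutation(m, x0_study, t_end = 6, dt = 1e-3)
  expect_equal(rowSums(p$X), rep(1, nrow(p$X)), tolerance = 1e-9)
  # running information flattens as the flow reaches its fixed point
  half <- p; half$X <- p$X[1:3001, ]; half$times <- p$times[1:3001]
  I_half <- path_functionals(half, m)$I
  I_full <- path_functionals(p, m)$I
  expect_gt(I_full, I_half)
  expect_lt(I_full - I_half, 0.05 * I_half + 1e-8)
  # estimator still recovers the rate with the mutation compensator
  expect_equal(rho_mle(p, m, use_streamed = FALSE)$raw, 3, tolerance = 0.02)
})

test_that("corrected estimator applies rectification and conventions", {
  # plain rectification on finite-information fits
  fit <- structure(list(estimate = 0, raw = -0.3, I_T = 1, Y = -0.3,
                        T_eff = 1, exploded = FALSE, S = NA_real_,
                        convention = "finite_information",
                        model = model_neutral()), class = "rho_mle")
  expect_equal(coef(fit), 0)
  m <- model_sym(rho = 0, theta = 5)
  paths <- batch_simulate(m, 30, seed = 31, dt = 1e-4, store_path = FALSE)
  fits <- lapply(paths, rho_mle)
  raws <- vapply(fits, `[[`, numeric(1), "raw")
  ests <- vapply(fits, `[[`, numeric(1), "estimate")
  expect_true(any(raws < 0))                  # some paths point below 0
  expect_equal(ests, pmax(0, raws))
  # exploded path: limit convention evaluates on [0, S), truth convention
  # records the generating rate exactly
  m1 <- model_sym(rho = 1, theta = 1)
  p <- simulate(m1, seed = 2, dt = 1e-4, t_end = 1)
  expect_true(p$exploded)
  f_lim <- rho_mle(p, convention = "limit_at_S")
  f_tru <- rho_mle(p, convention = "truth_assigned")
  expect_gte(f_lim$estimate, 0)
  expect_equal(f_lim$estimate, max(0, f_lim$raw))
  expect_identical(f_tru$estimate, 1)
  expect_identical(f_tru$convention, "truth_assigned")
})

test_that("generic linear-drift fit reproduces the recombination estimator", {
  m <- model_sym(rho = 5, theta = 5)
  p <- simulate(m, seed = 21, dt = 1e-3, t_end = 1, thin = 1)
  g <- generic_linear_mle(p, Z = score_recombination(m),
                          c_fun = function(x) drift_mutation(x, m))
  expect_equal(g$raw, rho_mle(p, use_streamed = FALSE)$raw, tolerance = 1e-10)
  expect_equal(g$I[1, 1], path_functionals(p)$I, tolerance = 1e-10)
  # quadratic log-likelihood: concave with maximizer Y/I
  expect_lt(-g$I[1, 1], 0)
  expect_equal(g$raw, g$Y / g$I[1, 1])
  # singular information reported with the deficient direction
  Zdup <- function(x) cbind(score_recombination(m)(x),
                            score_recombination(m)(x))
  expect_error(generic_linear_mle(p, Zdup), "deficient direction")
})

test_that("joint recombination-selection information is diagonal and the
           marginal selection estimator matches the joint fit", {
  msel <- wf_model(rho = 2, theta_A = 2, theta_B = 2,
                   selection = selection_genic(c(0.8, 0), "A"))
  p <- simulate(msel, seed = 41, dt = 1e-3, t_end = 1, thin = 1,
                joint_selection_allele = 1, selection_known = FALSE)
  # streamed cross-information vanishes (pointwise identity)
  expect_lt(abs(p$functionals$I_cross),
            1e-10 * max(p$functionals$I, p$functionals$I_sel))
  # joint r = 2 fit via the generic machinery
  Zjoint <- function(x) cbind(score_recombination(msel)(x),
                              score_selection_genic(msel, "A")(x)[, 1])
  g <- generic_linear_mle(p, Zjoint,
                          c_fun = function(x) drift_mutation(x, msel))
  expect_lt(abs(g$I[1, 2]), 1e-8 * sqrt(g$I[1, 1] * g$I[2, 2]))
  # marginal selection estimator equals the joint fit's second component
  s_hat <- selection_estimator(p, k = 1)
  expect_equal(s_hat$estimate, g$raw[2], tolerance = 1e-8)
  # and the recombination component equals the plain rho fit
  expect_equal(g$raw[1],
               rho_mle(p, use_streamed = FALSE,
                       model = wf_model(rho = 2, theta_A = 2, theta_B = 2))$raw,
               tolerance = 1e-10)
  # streamed selection functionals match the grid recomputation
  s_grid <- selection_estimator(p, k = 1, use_streamed = FALSE)
  expect_equal(s_hat$estimate, s_grid$estimate, tolerance = 1e-10)
})

test_that("selection estimator recovers the classical drift-only form", {
  # theta = 0: pure drift + selection; independent scalar oracle
  msel <- wf_model(rho = 0, selection = selection_genic(c(0.6, 0), "A"))
  p <- sim_full(msel, seed = 51, dt = 1e-3, t_end = 1)
  s_hat <- selection_estimator(p, k = 1, use_streamed = FALSE)
  # scalar oracle: 2 * (p_A(T) - p_A(0)) / int p_A (1 - p_A) dt, evaluated on
  # the same pre-explosion segment the estimator uses
  n <- p$functionals$n_eff + 1
  pA <- rowSums(p$X[seq_len(n), 1:2])
  denom <- sum(pA[-n] * (1 - pA[-n]) * diff(p$times[seq_len(n)]))
  expect_equal(s_hat$estimate, 2 * (pA[n] - pA[1]) / denom, tolerance = 1e-10)
  # constant marginal, no compensator: zero numerator
  pc <- make_const_path(c(0.3, 0.3, 0.2, 0.2))
  expect_equal(selection_estimator(pc, model_neutral(), k = 1,
                                   use_streamed = FALSE)$estimate, 0)
})

test_that("multi-locus estimators reduce to and extend the two-locus fit", {
  # ell = 2 reduction: joint and shared-rate equal the scalar fit
  m2 <- model_sym(rho = 2, theta = 5)
  p2 <- simulate(m2, seed = 61, dt = 1e-3, t_end = 1, thin = 1)
  scalar <- rho_mle(p2, use_streamed = FALSE)$raw
  g <- generic_linear_mle(p2, Z = function(x) {
    mm <- multilocus_marginals(x, c(2L, 2L), 1)
    matrix(mm$prefix * mm$suffix - x, ncol = 1)
  }, c_fun = function(x) drift_mutation(x, m2))
  expect_equal(g$raw, scalar, tolerance = 1e-10)
  # ell = 3 deterministic relaxation: shared-rate estimator recovers rho
  m3 <- wf_model(allele_counts = c(2L, 2L, 2L), rho = c(2, 2))
  p3 <- simulate(m3, seed = 1, x0 = rep(1 / 8, 8) + c(0.05, -0.02, -0.03, 0,
                                                      0.02, -0.02, 0.01, -0.01),
                 dt = 5e-4, t_end = 1, thin = 1, zero_noise = TRUE)
  fit_shared <- rho_mle(p3, shared_rate = TRUE)
  expect_equal(fit_shared$raw, 2, tolerance = 0.01)
  fit_joint <- rho_mle(p3)
  expect_equal(fit_joint$raw, c(2, 2), tolerance = 0.02)
  # I entries: D-form (streamed) vs expanded-form-minus-T identity
  f3 <- p3$functionals
  X <- p3$X; dts <- diff(p3$times)
  lef <- seq_len(nrow(X) - 1)
  I_exp <- matrix(0, 2, 2)
  for (j in 1:2) for (k in 1:2) {
    mmj <- t(apply(X[lef, ], 1, function(x) {
      mm <- multilocus_marginals(x, c(2L, 2L, 2L), j); mm$prefix * mm$suffix }))
    mmk <- t(apply(X[lef, ], 1, function(x) {
      mm <- multilocus_marginals(x, c(2L, 2L, 2L), k); mm$prefix * mm$suffix }))
    I_exp[j, k] <- sum(rowSums(mmj * mmk / X[lef, ]) * dts) - sum(dts)
  }
  expect_equal(f3$I, I_exp, tolerance = 1e-8)
  # stochastic ell = 3 run exercises the R stepper end to end
  p3s <- simulate(m3, seed = 2, x0 = rep(1 / 8, 8), dt = 2e-3, t_end = 0.5)
  expect_s3_class(rho_mle(p3s), "rho_mle")
})

test_that("error decomposition is exact on the discrete scheme", {
  m <- model_sym(rho = 5, theta = 5)
  p <- sim_full(m, seed = 71, dt = 1e-4, t_end = 0.5)
  ed <- error_decomposition(p)
  expect_equal(ed$predicted_error, ed$observed_error, tolerance = 1e-6)
  # quadratic variation of the martingale approximates the information
  expect_equal(ed$qv, ed$I, tolerance = 0.15)
  # zero-noise path: no martingale, no error
  p0 <- simulate(m, seed = 1, dt = 1e-3, t_end = 0.5, thin = 1,
                 store_increments = TRUE, zero_noise = TRUE)
  ed0 <- error_decomposition(p0)
  expect_equal(ed0$N, 0)
  expect_equal(ed0$predicted_error, 0)
})

test_that("running information is monotone and consistent with the batch fit", {
  m <- model_sym(rho = 5, theta = 5)
  p <- simulate(m, seed = 81, dt = 1e-4, t_end = 1, thin = 100)
  expect_true(all(diff(p$run$I) >= 0))
  expect_equal(p$run$I[length(p$run$I)], p$functionals$I)
  expect_equal(p$run$Y[length(p$run$Y)], p$functionals$Y)
  d <- run_path_diagnostics(5, 5, seed = 81, dt = 1e-4, thin = 100)
  last <- nrow(d$series)
  fit <- rho_mle(d$path)
  if (!d$path$exploded)
    expect_equal(d$series$rho_hat[last], fit$estimate, tolerance = 1e-12)
})

test_that("fit object methods behave like a classed model fit", {
  m <- model_sym(rho = 5, theta = 5)
  p <- simulate(m, seed = 91, dt = 1e-4, t_end = 1)
  fit <- rho_mle(p)
  expect_output(print(fit), "Recombination")
  expect_length(coef(fit), 1)
  if (!fit$exploded) {
    expect_equal(vcov(fit)[1, 1], 1 / fit$I_T)
    ll <- logLik(fit)
    expect_equal(as.numeric(ll),
                 fit$estimate * fit$Y - 0.5 * fit$estimate^2 * fit$I_T)
    # concavity: the quasi-log-likelihood is lower away from the maximizer
    off <- fit$raw + 1
    expect_gt(as.numeric(ll), off * fit$Y - 0.5 * off^2 * fit$I_T)
  }
  s <- summary(fit)
  expect_s3_class(s, "summary.rho_mle")
  expect_output(print(s), "error")
})
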