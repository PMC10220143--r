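# shared fixtures: the diallelic study state and models

x0_study <- c(2, 1, 1, 1) / 5

model_neutral <- function(rho = 0) wf_model(rho = rho)

model_sym <- function(rho = 0, theta = 1)
  wf_model(rho = rho, theta_A = theta, theta_B = theta)

# short full-resolution path with stored increments, for identity checks
sim_full <- function(model, seed = 1, dt = 1e-3, t_end = 0.5, ...) {
  simulate(model, seed = seed, x0 = x0_study, dt = dt, t_end = t_end,
           thin = 1, store_path = TRUE, store_increments = TRUE, ...)
}

random_interior <- function(n, d, seed = 42) {
  set.seed(seed)
  rsimplex(n, d)
}
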