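# deterministic in-code fixtures shared across test files

# tiny uncensored survival data with distinct times
tiny_surv <- function() {
  list(x = matrix(c(1, 2, 3), ncol = 1),
       time = c(1, 2, 3), event = c(1, 1, 1))
}

# small random Cox problem (q covariates, mixed censoring)
small_cox <- function(n = 60, q = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * q), n, q)
  lp <- drop(x %*% seq(-0.5, 0.5, length.out = q))
  time <- rexp(n, exp(lp))
  cens <- rexp(n, 0.3)
  list(x = x, time = pmin(time, cens), event = as.numeric(time <= cens))
}

# small complete mediation dataset from the generator
small_dataset <- function(n = 150, p = 60, seed = 42, censoring = 0.15) {
  generate_dataset(sim_config(n_subjects = n, n_mediators = p,
                              target_censoring = censoring, seed = seed))
}

# dataset with every effect switched off (complete null)
null_config <- function(n, p, seed) {
  sim_config(n_subjects = n, n_mediators = p,
             alpha_true = numeric(p), beta_true = numeric(p),
             phi_mediator = numeric(10), phi_outcome = numeric(10),
             theta = numeric(10), gamma = 0, seed = seed)
}
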