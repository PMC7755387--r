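# shared fixtures, all generated in code

# small simulated session: additive agent on a fresh schedule
make_session <- function(environment = "stable", alpha = 0.3, beta = 10,
                         phi = 0.5, seed = 1, n_trials = 80) {
  sched <- generate_schedule(task_config(environment, n_trials = n_trials),
                             seed = seed)
  simulate_agent(sched, choice_params(alpha, beta, phi, model = "additive"),
                 seed = seed + 1000)
}

# session with ratings generated from the probability + PPE model
make_rated_session <- function(environment = "stable", alpha = 0.3,
                               w_p = 0.74, w_ppe = 1.32, gamma = 0.59,
                               noise_sd = 0.6, seed = 1, scale = "z", ...) {
  ses <- make_session(environment, alpha = alpha, seed = seed)
  hp <- happiness_params("p_ppe",
                         weights = c(p_hat_centered = w_p, ppe_hat = w_ppe),
                         gamma = gamma)
  simulate_ratings(ses, hp, alpha = alpha, noise_sd = noise_sd,
                   scale = scale, seed = seed + 2000, ...)
}

# direct (non-recursive) decayed sum, the brute-force oracle
decayed_sum_direct <- function(series, gamma, t) {
  sum(gamma^(t - seq_len(t)) * series[seq_len(t)])
}
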