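# Shared fixtures: small configs and simulated agents, all built in code.

tiny_cohort_config <- function(...) {
  cohort_config(
    group_sizes = c(low_mdq = 3, high_mdq = 3, bd_lithium = 2,
                    bd_placebo = 2),
    days_volunteer = 6, days_baseline = 2, days_post = 4, ...
  )
}

# Stacked sessions from a single agent with known parameters; returns a
# trial table usable by the model-free and fitting layers.
agent_trials <- function(lambda = 1, gamma = 0, beta = 0.2, n_sessions = 20,
                         n_trials = 20, id = "a") {
  purrr::map(seq_len(n_sessions), function(i) {
    simulate_session(lambda, gamma, beta, n_trials) |>
      dplyr::mutate(participant_id = id, day = i)
  }) |> dplyr::bind_rows()
}

# Independent per-trial likelihood oracle: plain loop, no shared code with
# session_log_likelihood beyond arithmetic.
brute_force_loglik <- function(session, lambda, gamma, beta) {
  ll <- 0
  prev <- 0
  ord <- order(session$trial)
  for (i in ord) {
    u_l <- session$p_win_left[i] * session$mag_win_left[i] -
      (lambda + gamma * prev) * (1 - session$p_win_left[i]) *
        session$mag_loss_left[i]
    u_r <- session$p_win_right[i] * session$mag_win_right[i] -
      (lambda + gamma * prev) * (1 - session$p_win_right[i]) *
        session$mag_loss_right[i]
    p_l <- 1 / (1 + exp(beta * (u_r - u_l)))
    p <- if (session$choice[i] == "L") p_l else 1 - p_l
    ll <- ll + log(max(p, 1e-12))
    prev <- sign(session$outcome[i])
  }
  ll
}

pair_ev_gap <- function(pairs) {
  ev <- function(p, w, l) p * w - (1 - p) * l
  abs(ev(pairs$p_win_left, pairs$mag_win_left, pairs$mag_loss_left) -
        ev(pairs$p_win_right, pairs$mag_win_right, pairs$mag_loss_right))
}

g_linear_row <- function(fit) {
  td <- generics::tidy(fit)
  td[td$term == "g_linear" & td$submodel == "mean", ]
}
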