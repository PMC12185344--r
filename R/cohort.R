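#' Cohort-simulation configuration
#'
#' Describes the synthetic longitudinal study: group sizes and testing
#' schedules mirroring the two-study design (two volunteer groups screened by
#' the Mood Disorder Questionnaire plus a bipolar-disorder trial arm
#' randomised to lithium or placebo), group-level decision-model parameters,
#' their between-participant and session-to-session variability, and the mood
#' model.
#'
#' Defaults encode the study design this generator emulates: 37/40/19/16
#' participants, 50 daily sessions for volunteers, a 14-day baseline plus
#' 42-day treatment phase for patients, 20 trials per session. Parameter
#' means follow the qualitative group structure reported for such cohorts: a
#' step-change drop in loss sensitivity `lambda` for patients, a continuous
#' decrease of the outcome-history weight `gamma` along the
#' low-MDQ/high-MDQ/bipolar gradient, equal inverse temperature. Lithium
#' effects default to zero. PANAS mood-instability SDs increase along the
#' gradient; post-minus-pre happiness couples to the session's summed outcome;
#' in the patient group same-day positive mood reduces choice noisiness
#' (raises effective `log beta`).
#'
#' @param group_sizes Named integer vector: `low_mdq`, `high_mdq`,
#'   `bd_lithium`, `bd_placebo`.
#' @param days_volunteer Sessions per volunteer.
#' @param days_baseline,days_post Pre-randomisation and treatment-phase
#'   sessions per patient.
#' @param n_trials Trials per session.
#' @param param_means Tibble with columns `group` (`low_mdq`, `high_mdq`,
#'   `bd`), `lambda`, `gamma`, `log_beta`: group-level parameter means.
#' @param between_sd,within_sd Named vectors (`lambda`, `gamma`, `log_beta`):
#'   between-participant and session-to-session SDs.
#' @param day_drift Named vector: linear per-day drift added to each
#'   parameter (units per day).
#' @param drug_effect Named vector: additive shift applied to lithium-arm
#'   parameters in the post phase.
#' @param panas_sd Named vector by group: within-participant daily SD of the
#'   PANAS scales (the mood-instability parameter).
#' @param panas_baseline Named vector `c(pos = , neg = )`: population mean
#'   PANAS scores.
#' @param panas_baseline_sd Between-participant SD of PANAS baselines.
#' @param vas_baseline,vas_baseline_sd Happiness-VAS pre-session baseline
#'   mean and between-participant SD (0-100 scale).
#' @param vas_change_sd Residual SD of the post-minus-pre VAS change.
#' @param outcome_coupling VAS points of post-minus-pre happiness change per
#'   SD of the session's summed net outcome.
#' @param mood_noisiness_coupling Named vector by group: shift in effective
#'   session `log beta` per within-participant SD of same-day positive PANAS.
#' @param missing_rate Probability a scheduled session is missing at random.
#' @param age_mean,age_sd,female_prob Named vectors over the four recruitment
#'   groups: demographics used as covariates downstream.
#' @param task A [task_gen_config()] for the stimuli.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(low_mdq = 37, high_mdq = 40,
                                          bd_lithium = 19, bd_placebo = 16),
                          days_volunteer = 50,
                          days_baseline = 14,
                          days_post = 42,
                          n_trials = 20,
                          param_means = tibble(
                            group = c("low_mdq", "high_mdq", "bd"),
                            lambda = c(1.2, 1.15, 0.9),
                            gamma = c(0.10, 0.05, 0.0),
                            log_beta = log(0.1)
                          ),
                          between_sd = c(lambda = 0.3, gamma = 0.15,
                                         log_beta = 0.4),
                          within_sd = c(lambda = 0.4, gamma = 0.3,
                                        log_beta = 0.3),
                          day_drift = c(lambda = 0, gamma = 0, log_beta = 0),
                          drug_effect = c(lambda = 0, gamma = 0, log_beta = 0),
                          panas_sd = c(low_mdq = 1.5, high_mdq = 2.0, bd = 2.5),
                          panas_baseline = c(pos = 30, neg = 15),
                          panas_baseline_sd = 4,
                          vas_baseline = 60,
                          vas_baseline_sd = 10,
                          vas_change_sd = 9.1,
                          outcome_coupling = 4.2,
                          mood_noisiness_coupling = c(low_mdq = 0,
                                                      high_mdq = 0, bd = 0.18),
                          missing_rate = 0,
                          age_mean = c(low_mdq = 25.0, high_mdq = 25.0,
                                       bd_lithium = 28.8, bd_placebo = 35.1),
                          age_sd = c(low_mdq = 6.6, high_mdq = 7.1,
                                     bd_lithium = 9.8, bd_placebo = 13.8),
                          female_prob = c(low_mdq = 0.65, high_mdq = 0.675,
                                          bd_lithium = 0.58, bd_placebo = 0.56),
                          task = task_gen_config()) {
  if (any(group_sizes < 0)) abort("Group sizes must be >= 0.")
  if (any(c(between_sd, within_sd, panas_sd) < 0)) abort("SDs must be >= 0.")
  if (days_volunteer < 1 || days_baseline + days_post < 1) {
    abort("Each participant needs at least one session day.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Gradient group levels
#'
#' The ordered three-level "bipolar gradient": low MDQ <= high MDQ <= bipolar
#' disorder.
#' @return Character vector of the ordered levels.
#' @export
gradient_levels <- function() c("low_mdq", "high_mdq", "bd")

#' Draw the participant layer of a synthetic cohort
#'
#' One row per participant: recruitment group, gradient group, trial arm,
#' demographics and participant-level decision-model parameters.
#'
#' @param config A [cohort_config()].
#' @return A tibble.
#' @export
simulate_participants <- function(config) {
  recruit <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(recruit)
  group <- ifelse(recruit %in% c("bd_lithium", "bd_placebo"), "bd", recruit)
  arm <- dplyr::case_when(recruit == "bd_lithium" ~ "lithium",
                          recruit == "bd_placebo" ~ "placebo",
                          TRUE ~ "none")
  means <- config$param_means[match(group, config$param_means$group), ]
  tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    recruit_group = recruit,
    group = factor(group, levels = gradient_levels(), ordered = TRUE),
    arm = arm,
    age = rnorm(n, config$age_mean[recruit], config$age_sd[recruit]),
    gender = ifelse(runif(n) < config$female_prob[recruit], "F", "M"),
    lambda_i = rnorm(n, means$lambda, config$between_sd[["lambda"]]),
    gamma_i = rnorm(n, means$gamma, config$between_sd[["gamma"]]),
    log_beta_i = rnorm(n, means$log_beta, config$between_sd[["log_beta"]]),
    panas_pos_i = rnorm(n, config$panas_baseline[["pos"]],
                        config$panas_baseline_sd),
    panas_neg_i = rnorm(n, config$panas_baseline[["neg"]],
                        config$panas_baseline_sd),
    vas_i = rnorm(n, config$vas_baseline, config$vas_baseline_sd)
  )
}

#' Draw the session layer: per-day true parameters and pre-session mood
#'
#' Expands participants to one row per scheduled session day, draws daily
#' PANAS and pre-session happiness VAS, applies day drift, the lithium
#' post-phase shift, session-to-session parameter jitter and the same-day
#' mood-to-noisiness coupling. The returned `lambda`, `gamma`, `log_beta`
#' columns are the effective session-level ground truth that generates (and
#' that session fitting tries to recover from) that session's choices.
#'
#' @param config A [cohort_config()].
#' @param participants Optional participant table from
#'   [simulate_participants()]; drawn fresh if omitted.
#' @return A tibble, one row per participant-day.
#' @export
simulate_session_params <- function(config, participants = NULL) {
  participants <- participants %||% simulate_participants(config)
  days_of <- function(recruit) {
    if (recruit %in% c("bd_lithium", "bd_placebo")) {
      config$days_baseline + config$days_post
    } else {
      config$days_volunteer
    }
  }
  sess <- participants |>
    mutate(n_days = purrr::map_int(.data$recruit_group,
                                   \(g) as.integer(days_of(g)))) |>
    tidyr::uncount(.data$n_days, .id = "day") |>
    mutate(
      phase = dplyr::case_when(
        .data$arm == "none" ~ "none",
        .data$day <= config$days_baseline ~ "pre",
        TRUE ~ "post"
      )
    )
  if (config$missing_rate > 0) {
    sess <- sess |> filter(runif(n()) >= config$missing_rate)
  }
  n <- nrow(sess)
  lith_post <- sess$arm == "lithium" & sess$phase == "post"
  sess |>
    mutate(
      panas_pos = rnorm(n, .data$panas_pos_i,
                        config$panas_sd[as.character(.data$group)]),
      panas_neg = rnorm(n, .data$panas_neg_i,
                        config$panas_sd[as.character(.data$group)]),
      vas_pre = pmin(pmax(rnorm(n, .data$vas_i, 3), 0), 100),
      lambda = .data$lambda_i +
        config$day_drift[["lambda"]] * (.data$day - 1) +
        lith_post * config$drug_effect[["lambda"]] +
        rnorm(n, 0, config$within_sd[["lambda"]]),
      gamma = .data$gamma_i +
        config$day_drift[["gamma"]] * (.data$day - 1) +
        lith_post * config$drug_effect[["gamma"]] +
        rnorm(n, 0, config$within_sd[["gamma"]]),
      log_beta = .data$log_beta_i +
        config$day_drift[["log_beta"]] * (.data$day - 1) +
        lith_post * config$drug_effect[["log_beta"]] +
        rnorm(n, 0, config$within_sd[["log_beta"]]) +
        config$mood_noisiness_coupling[as.character(.data$group)] *
          (.data$panas_pos - .data$panas_pos_i) /
          config$panas_sd[as.character(.data$group)]
    ) |>
    select(-"n_days")
}

#' Simulate one session of choices from known parameters
#'
#' Draws `n_trials` gamble pairs from the task generator and plays them with
#' the softmax agent, propagating the previous-outcome sign from each
#' realized outcome to the next trial (first trial carries no history).
#'
#' @param lambda,gamma,beta Agent parameters.
#' @param n_trials Number of trials (default 20).
#' @param config A [task_gen_config()].
#' @return A trial tibble with gamble attributes, `trial`, `prev_sign`,
#'   `choice` and `outcome`.
#' @export
simulate_session <- function(lambda, gamma, beta, n_trials = 20,
                             config = task_gen_config()) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  pairs <- generate_option_pairs(n_trials, config)
  sim <- simulate_trials_grouped(pairs, session_id = rep(1L, n_trials),
                                 lambda = lambda, gamma = gamma, beta = beta)
  sim |> mutate(trial = row_number()) |>
    select("trial", dplyr::starts_with("p_win"), dplyr::starts_with("mag_"),
           "prev_sign", "choice", "outcome")
}

# Vectorised sequential simulation: `pairs` holds stacked trials for many
# sessions; trials of one session must be contiguous and in order. lambda,
# gamma, beta are per-trial vectors (recycled from per-session values).
simulate_trials_grouped <- function(pairs, session_id, lambda, gamma, beta) {
  n <- nrow(pairs)
  lambda <- rep_len(lambda, n); gamma <- rep_len(gamma, n)
  beta <- rep_len(beta, n)
  first <- !duplicated(session_id)
  prev_sign <- numeric(n)
  choice <- character(n)
  outcome <- numeric(n)
  # positions of the t-th trial of every session, iterated in lockstep
  ord <- stats::ave(seq_len(n), session_id, FUN = seq_along)
  for (t in seq_len(max(ord))) {
    idx <- which(ord == t)
    if (t > 1) {
      prev_idx <- idx - 1L
      prev_sign[idx] <- sign(outcome[prev_idx])
    }
    u_l <- option_utility(pairs$p_win_left[idx], pairs$mag_win_left[idx],
                          pairs$mag_loss_left[idx], lambda[idx], gamma[idx],
                          prev_sign[idx])
    u_r <- option_utility(pairs$p_win_right[idx], pairs$mag_win_right[idx],
                          pairs$mag_loss_right[idx], lambda[idx], gamma[idx],
                          prev_sign[idx])
    p_l <- choice_prob_left(u_l, u_r, beta[idx])
    ch_l <- runif(length(idx)) < p_l
    choice[idx] <- ifelse(ch_l, "L", "R")
    p_win_ch <- ifelse(ch_l, pairs$p_win_left[idx], pairs$p_win_right[idx])
    won <- runif(length(idx)) < p_win_ch
    outcome[idx] <- ifelse(
      won,
      ifelse(ch_l, pairs$mag_win_left[idx], pairs$mag_win_right[idx]),
      -ifelse(ch_l, pairs$mag_loss_left[idx], pairs$mag_loss_right[idx])
    )
  }
  pairs |> mutate(prev_sign = prev_sign, choice = choice, outcome = outcome)
}

draw_vas_post <- function(mood, config) {
  z_net <- as.numeric(scale(mood$net_outcome))
  if (all(is.na(z_net)) || sd(mood$net_outcome) == 0) {
    z_net <- rep(0, nrow(mood))
    warn("Net outcomes are constant: happiness-outcome coupling is unidentifiable in this cohort.")
  }
  mood |>
    mutate(vas_post = pmin(pmax(
      .data$vas_pre + config$outcome_coupling * z_net +
        rnorm(n(), 0, config$vas_change_sd), 0), 100))
}

#' Generate a daily mood series coupled to session outcomes
#'
#' Given a session table (rows = participant-days) that carries the summed
#' session net outcome, draws daily PANAS scores around participant baselines
#' with group-specific SD, a pre-session happiness VAS, and a post-session
#' VAS equal to pre plus the outcome coupling (VAS points per SD of net
#' outcome, standardised across the supplied sessions) plus noise.
#'
#' @param sessions Tibble with `participant_id`, `group`, `day` and
#'   `net_outcome` columns; `group` must use [gradient_levels()].
#' @param config A [cohort_config()].
#' @return A mood tibble: `participant_id`, `group`, `day`, `panas_pos`,
#'   `panas_neg`, `vas_pre`, `vas_post`.
#' @export
generate_mood_series <- function(sessions, config = cohort_config()) {
  base <- sessions |>
    distinct(.data$participant_id) |>
    mutate(
      panas_pos_i = rnorm(n(), config$panas_baseline[["pos"]],
                          config$panas_baseline_sd),
      panas_neg_i = rnorm(n(), config$panas_baseline[["neg"]],
                          config$panas_baseline_sd),
      vas_i = rnorm(n(), config$vas_baseline, config$vas_baseline_sd)
    )
  mood <- sessions |>
    left_join(base, by = "participant_id") |>
    mutate(
      panas_pos = rnorm(n(), .data$panas_pos_i,
                        config$panas_sd[as.character(.data$group)]),
      panas_neg = rnorm(n(), .data$panas_neg_i,
                        config$panas_sd[as.character(.data$group)]),
      vas_pre = pmin(pmax(rnorm(n(), .data$vas_i, 3), 0), 100)
    )
  mood <- draw_vas_post(mood, config)
  mood |>
    select("participant_id", "group", "day", "panas_pos", "panas_neg",
           "vas_pre", "vas_post")
}

#' Generate a full synthetic cohort
#'
#' Composes the participant, session-parameter, stimulus, choice and mood
#' layers into a tidy longitudinal dataset: a trial table in the package's
#' CSV dialect, a daily mood table, and the session-wise ground-truth
#' parameter table against which recovery can be scored. Fully reproducible
#' under `set.seed()`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `gamble_cohort`: a list with tibbles `trials`,
#'   `mood`, `truth` (session-wise true parameters) and `participants`.
#' @examples
#' cfg <- cohort_config(group_sizes = c(low_mdq = 2, high_mdq = 2,
#'                                      bd_lithium = 1, bd_placebo = 1),
#'                      days_volunteer = 3, days_baseline = 1, days_post = 2)
#' set.seed(1)
#' cohort <- generate_cohort(cfg)
#' @export
generate_cohort <- function(config = cohort_config()) {
  sess <- simulate_session_params(config)
  sess$session_id <- seq_len(nrow(sess))
  n_tr <- config$n_trials
  pairs <- generate_option_pairs(nrow(sess) * n_tr, config$task)
  sid <- rep(sess$session_id, each = n_tr)
  sim <- simulate_trials_grouped(
    pairs, sid,
    lambda = rep(sess$lambda, each = n_tr),
    gamma = rep(sess$gamma, each = n_tr),
    beta = rep(exp(sess$log_beta), each = n_tr)
  )
  sim$session_id <- sid
  sim <- sim |>
    group_by(.data$session_id) |>
    mutate(trial = row_number()) |>
    ungroup()
  keys <- sess |>
    select("session_id", "participant_id", "group", "arm", "phase", "day")
  trials <- sim |>
    left_join(keys, by = "session_id") |>
    mutate(group = as.character(.data$group)) |>
    select("participant_id", "group", "arm", "phase", "day", "trial",
           "p_win_left", "mag_win_left", "mag_loss_left",
           "p_win_right", "mag_win_right", "mag_loss_right",
           "choice", "outcome")
  net <- sim |>
    group_by(.data$session_id) |>
    summarise(net_outcome = sum(.data$outcome), .groups = "drop")
  sess <- sess |> left_join(net, by = "session_id")
  mood <- draw_vas_post(sess, config) |>
    mutate(group = as.character(.data$group)) |>
    select("participant_id", "group", "day", "panas_pos", "panas_neg",
           "vas_pre", "vas_post")
  truth <- sess |>
    mutate(group = as.character(.data$group), beta = exp(.data$log_beta)) |>
    select("participant_id", "group", "arm", "phase", "day", "age", "gender",
           "lambda", "gamma", "log_beta", "beta", "net_outcome", "panas_pos")
  participants <- sess |>
    distinct(.data$participant_id, .data$recruit_group, .data$group,
             .data$arm, .data$age, .data$gender) |>
    mutate(group = as.character(.data$group))
  structure(list(trials = trials, mood = mood, truth = truth,
                 participants = participants, config = config),
            class = "gamble_cohort")
}

#' @export
print.gamble_cohort <- function(x, ...) {
  cat("<gamble_cohort>\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  sessions:    ", nrow(x$truth), "\n")
  cat("  trials:      ", nrow(x$trials), "\n")
  invisible(x)
}
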