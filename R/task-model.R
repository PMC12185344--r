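#' The wheel-of-fortune decision model
#'
#' A gamble ("wheel of fortune") option shows a win probability `p_win`, a win
#' magnitude `mag_win` (points, 10-200) and a loss magnitude `mag_loss`
#' (points, 10-200). Its subjective utility is
#'
#' \deqn{U = p_{win} \cdot mag_{win} - (\lambda + \gamma \cdot s) \cdot
#'       (1 - p_{win}) \cdot mag_{loss}}
#'
#' where `lambda` weights the loss relative to the reward component
#' (`lambda = 1` is reward/loss symmetry), `gamma` modulates the loss weight by
#' the previous trial's outcome, and `s` codes that outcome: `+1` after a win,
#' `-1` after a loss, `0` on the first trial of a session (no history).
#' `gamma > 0` means increased loss sensitivity after a win.
#'
#' Utilities are in raw points; no rescaling is applied, so the inverse
#' temperature of [choice_prob_left()] has units of 1/points.
#'
#' @param p_win Win probability in \[0, 1\]. Vectorised.
#' @param mag_win,mag_loss Win/loss magnitudes in points (> 0). Vectorised.
#' @param lambda Loss sensitivity weight.
#' @param gamma Outcome-history weight (default 0).
#' @param prev_sign Previous-outcome code in \{-1, 0, +1\} (default 0).
#'
#' @return Numeric vector of utilities (signed points).
#' @examples
#' option_utility(0.7, 100, 50, lambda = 1)            # plain expected utility
#' option_utility(0.7, 100, 50, lambda = 1, gamma = 0.2, prev_sign = 1)
#' @export
option_utility <- function(p_win, mag_win, mag_loss, lambda, gamma = 0,
                           prev_sign = 0) {
  if (any(p_win < 0 | p_win > 1, na.rm = TRUE)) {
    abort("`p_win` must lie in [0, 1].")
  }
  if (!all(prev_sign %in% c(-1, 0, 1))) {
    abort("`prev_sign` must be -1, 0 or +1.")
  }
  p_win * mag_win - (lambda + gamma * prev_sign) * (1 - p_win) * mag_loss
}

#' Softmax probability of choosing the left option
#'
#' \deqn{p(left) = 1 / (1 + e^{\beta (U_{right} - U_{left})})}
#'
#' `beta` is the inverse temperature (1/points): `beta = 0` gives random
#' choice, large `beta` near-deterministic choice of the higher-utility
#' option. The exponent is clipped at |beta * dU| = 500 so the probability is
#' always finite and strictly inside (0, 1) in double precision arithmetic's
#' meaningful range.
#'
#' @param u_left,u_right Option utilities (points). Vectorised.
#' @param beta Inverse temperature, must be >= 0.
#' @return Probability of choosing left, in (0, 1).
#' @examples
#' choice_prob_left(55, 45, beta = 0.1)   # 1 / (1 + exp(-1))
#' @export
choice_prob_left <- function(u_left, u_right, beta) {
  if (any(beta < 0)) abort("`beta` must be non-negative.")
  z <- beta * (u_right - u_left)
  z <- pmin(pmax(z, -500), 500)
  1 / (1 + exp(z))
}

#' Simulate one trial of the task
#'
#' Draws the choice from the softmax rule and resolves the chosen wheel: a win
#' (`+mag_win` of the chosen option) with its win probability, else a loss
#' (`-mag_loss`).
#'
#' @param left,right Lists or one-row data frames with `p_win`, `mag_win`,
#'   `mag_loss`.
#' @param lambda,gamma,beta Model parameters (see [option_utility()]).
#' @param prev_sign Previous-outcome code in \{-1, 0, +1\}.
#' @return A list with `choice` (`"L"` or `"R"`) and `outcome` (signed points).
#' @export
simulate_trial <- function(left, right, lambda, gamma, beta, prev_sign = 0) {
  u_l <- option_utility(left$p_win, left$mag_win, left$mag_loss,
                        lambda, gamma, prev_sign)
  u_r <- option_utility(right$p_win, right$mag_win, right$mag_loss,
                        lambda, gamma, prev_sign)
  p_l <- choice_prob_left(u_l, u_r, beta)
  choice <- if (runif(1) < p_l) "L" else "R"
  opt <- if (choice == "L") left else right
  won <- runif(1) < opt$p_win
  outcome <- if (won) opt$mag_win else -opt$mag_loss
  list(choice = choice, outcome = outcome)
}

#' Recompute previous-outcome signs along a session
#'
#' Adds (or overwrites) a `prev_sign` column: 0 on the first trial of each
#' participant-day session, then the sign of the previous trial's realized
#' outcome. History never crosses session (day) boundaries.
#'
#' @param trials A trial table with at least `participant_id`, `day`, `trial`
#'   and `outcome` columns.
#' @return The table with a `prev_sign` column, ordered within sessions.
#' @export
add_prev_sign <- function(trials) {
  keys <- intersect(c("participant_id", "day"), names(trials))
  out <- trials |> group_by(across(all_of(keys)))
  if ("trial" %in% names(trials)) {
    out <- out |> arrange(.data$trial, .by_group = TRUE)
  }
  out |>
    mutate(prev_sign = dplyr::coalesce(sign(lag(.data$outcome)), 0)) |>
    ungroup()
}

trial_choice_probs <- function(trials, lambda, gamma, beta) {
  u_l <- option_utility(trials$p_win_left, trials$mag_win_left,
                        trials$mag_loss_left, lambda, gamma, trials$prev_sign)
  u_r <- option_utility(trials$p_win_right, trials$mag_win_right,
                        trials$mag_loss_right, lambda, gamma, trials$prev_sign)
  choice_prob_left(u_l, u_r, beta)
}

#' Log-likelihood of one session's choices
#'
#' Sum over trials of the log probability the model assigns to the observed
#' choice. `prev_sign` is recomputed from the session's own outcome sequence;
#' if the table already carries a `prev_sign` column that disagrees with the
#' recomputed chain, that is a data-integrity error. Probabilities are floored
#' at 1e-12 before taking logs.
#'
#' @param session Trial table for a single session (one participant-day),
#'   with gamble columns, `choice` (`"L"`/`"R"`) and `outcome`.
#' @param lambda,gamma,beta Model parameters.
#' @return Log-likelihood (<= 0).
#' @export
session_log_likelihood <- function(session, lambda, gamma, beta) {
  if (nrow(session) == 0) abort("Empty session: no trials to score.")
  if (anyNA(session$choice)) abort("Session has unrecorded choices.")
  stored <- if ("prev_sign" %in% names(session)) session$prev_sign else NULL
  session <- add_prev_sign(session)
  if (!is.null(stored) && !isTRUE(all.equal(stored, session$prev_sign))) {
    abort("Stored `prev_sign` disagrees with the session's outcome sequence.")
  }
  p_l <- trial_choice_probs(session, lambda, gamma, beta)
  p_obs <- ifelse(session$choice == "L", p_l, 1 - p_l)
  sum(log(pmax(p_obs, 1e-12)))
}
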