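#' Model-free behavioural statistics
#'
#' These functions quantify task behaviour without fitting the decision
#' model: a choice curve over displayed utility differences, per-dimension
#' (win vs loss) sensitivity, the outcome-history contrast, and the
#' predictive accuracy of fitted parameters. Displayed utilities use the
#' `lambda = 1, gamma = 0` convention (exactly what the participant sees:
#' probability times magnitude), so first trials are included — there is no
#' history term in a displayed utility.
#'
#' @name model_free
NULL

display_deltas <- function(trials) {
  trials |>
    mutate(
      d_rew = .data$p_win_left * .data$mag_win_left -
        .data$p_win_right * .data$mag_win_right,
      d_loss = (1 - .data$p_win_left) * .data$mag_loss_left -
        (1 - .data$p_win_right) * .data$mag_loss_right,
      d_util = .data$d_rew - .data$d_loss,
      chose_left = .data$choice == "L"
    )
}

quantile_bin <- function(x, n_bins) {
  brk <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 3) abort("Too few distinct values to form bins.")
  cut(x, breaks = brk, include.lowest = TRUE)
}

#' Choice curve over binned utility differences
#'
#' Bins trials by the displayed utility difference between the left and right
#' option (reward utility minus loss utility, left minus right) into
#' equal-count bins and reports the fraction of left choices per bin. A
#' value-sensitive chooser produces a rising curve.
#'
#' @param trials Trial table.
#' @param n_bins Number of quantile bins (>= 2; default 7).
#' @return A tibble of class `choice_curve`: `bin`, `bin_mid` (mean
#'   within-bin utility difference), `n`, `frac_left`.
#' @export
bin_choice_curve <- function(trials, n_bins = 7) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  out <- display_deltas(trials) |>
    mutate(bin = quantile_bin(.data$d_util, n_bins)) |>
    group_by(.data$bin) |>
    summarise(bin_mid = mean(.data$d_util), n = n(),
              frac_left = mean(.data$chose_left), .groups = "drop") |>
    arrange(.data$bin_mid)
  class(out) <- c("choice_curve", class(out))
  out
}

#' Win- and loss-dimension sensitivity
#'
#' Splits value sensitivity by dimension. Display curves are marginal:
#' fraction of left choices binned separately over the reward-utility
#' difference and the loss-utility difference. Slopes, however, come from a
#' joint per-participant logistic regression of choice on both differences —
#' the task deliberately matches expected values, which makes the two
#' differences strongly correlated, so marginal slopes would confound the
#' dimensions. The loss slope is sign-flipped so that, like the win slope,
#' larger means more sensitive; under the generative model the win slope
#' estimates `beta` and the loss slope `beta * lambda`.
#'
#' @param trials Trial table.
#' @param n_bins Quantile bins per dimension for the display curves.
#' @return A list of class `dimension_sensitivity`: `curves` (per-dimension
#'   binned fractions) and `slopes` (per participant: `win_slope`,
#'   `loss_slope`, `slope_diff = win - loss`).
#' @export
dimension_sensitivity <- function(trials, n_bins = 7) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  dd <- display_deltas(trials)
  curves <- purrr::map(c(win = "d_rew", loss = "d_loss"), function(col) {
    dd |>
      mutate(bin = quantile_bin(.data[[col]], n_bins)) |>
      group_by(.data$bin) |>
      summarise(bin_mid = mean(.data[[col]]), n = n(),
                frac_left = mean(.data$chose_left), .groups = "drop")
  }) |> bind_rows(.id = "dimension")
  slopes <- dd |>
    group_by(.data$participant_id) |>
    summarise(fit = list(tryCatch(
      suppressWarnings(glm(chose_left ~ d_rew + d_loss, family = binomial(),
                           data = dplyr::pick(dplyr::everything()))),
      error = function(e) NULL)), .groups = "drop") |>
    mutate(
      win_slope = purrr::map_dbl(.data$fit,
                                 \(f) if (is.null(f)) NA_real_ else coef(f)[["d_rew"]]),
      loss_slope = purrr::map_dbl(.data$fit,
                                  \(f) if (is.null(f)) NA_real_ else -coef(f)[["d_loss"]]),
      slope_diff = .data$win_slope - .data$loss_slope
    ) |>
    select(-"fit")
  structure(list(curves = curves, slopes = slopes),
            class = "dimension_sensitivity")
}

#' Outcome-history contrast
#'
#' The model-free signature of outcome-history adaptation: on trials where
#' the two options differ most in loss utility (top `extreme_fraction` of
#' |loss-utility difference|; a multiplicative change in loss weighting
#' matters most there), the fraction of choices of the lower-loss-utility
#' option after a previous win minus after a previous loss, per participant.
#' Positive values mean more loss avoidance after wins (`gamma > 0`). First
#' trials of sessions are excluded (no previous outcome); trials with equal
#' loss utilities are excluded (the lower-loss label is undefined).
#' Participants with an empty after-win or after-loss cell are flagged and
#' get `NA`.
#'
#' @param trials Trial table.
#' @param extreme_fraction Fraction of trials kept, by |loss-utility
#'   difference| (default 0.25).
#' @return A tibble: `participant_id`, `contrast`, `n_after_win`,
#'   `n_after_loss`, `flagged`.
#' @export
outcome_history_contrast <- function(trials, extreme_fraction = 0.25) {
  if (extreme_fraction <= 0 || extreme_fraction > 1) {
    abort("`extreme_fraction` must lie in (0, 1].")
  }
  dd <- add_prev_sign(trials) |>
    display_deltas() |>
    filter(.data$prev_sign != 0, .data$d_loss != 0)
  thr <- quantile(abs(dd$d_loss), 1 - extreme_fraction)
  dd <- dd |>
    filter(abs(.data$d_loss) >= thr) |>
    mutate(chose_lower_loss = (.data$d_loss < 0) == .data$chose_left)
  out <- dd |>
    group_by(.data$participant_id) |>
    summarise(
      p_after_win = mean(.data$chose_lower_loss[.data$prev_sign == 1]),
      p_after_loss = mean(.data$chose_lower_loss[.data$prev_sign == -1]),
      n_after_win = sum(.data$prev_sign == 1),
      n_after_loss = sum(.data$prev_sign == -1),
      .groups = "drop"
    ) |>
    mutate(contrast = .data$p_after_win - .data$p_after_loss,
           flagged = .data$n_after_win == 0 | .data$n_after_loss == 0) |>
    select("participant_id", "contrast", "n_after_win", "n_after_loss",
           "flagged")
  if (any(out$flagged)) {
    warn("Some participants have an empty after-win or after-loss cell; their contrast is NA.")
  }
  out
}

#' Predictive accuracy of session fits
#'
#' Fraction of trials on which the fitted model's modal predicted choice
#' (probability > 0.5) matches the observed choice; exact ties count 1/2.
#' Sessions without a matching fit are skipped with a warning.
#'
#' @param trials Trial table.
#' @param fits Session-fits table from [fit_sessions()].
#' @return A tibble with per-group rows plus an `"all"` row: `group`,
#'   `n_trials`, `accuracy`.
#' @export
predictive_accuracy <- function(trials, fits) {
  keyed <- trials |>
    left_join(fits |> select("participant_id", "day", "lambda_mean",
                             "gamma_mean", "log_beta_mean"),
              by = c("participant_id", "day"))
  miss <- keyed |> filter(is.na(.data$lambda_mean))
  if (nrow(miss) > 0) {
    warn(sprintf("%d trials belong to sessions without a fit; skipped.",
                 nrow(miss)))
    keyed <- keyed |> filter(!is.na(.data$lambda_mean))
  }
  scored <- keyed |>
    add_prev_sign() |>
    mutate(
      p_left = choice_prob_left(
        option_utility(.data$p_win_left, .data$mag_win_left,
                       .data$mag_loss_left, .data$lambda_mean,
                       .data$gamma_mean, .data$prev_sign),
        option_utility(.data$p_win_right, .data$mag_win_right,
                       .data$mag_loss_right, .data$lambda_mean,
                       .data$gamma_mean, .data$prev_sign),
        exp(.data$log_beta_mean)),
      p_obs = ifelse(.data$choice == "L", .data$p_left, 1 - .data$p_left),
      score = ifelse(.data$p_obs > 0.5, 1, ifelse(.data$p_obs == 0.5, 0.5, 0))
    )
  per_group <- scored |>
    group_by(group = as.character(.data$group)) |>
    summarise(n_trials = n(), accuracy = mean(.data$score), .groups = "drop")
  bind_rows(per_group,
            tibble(group = "all", n_trials = nrow(scored),
                   accuracy = mean(scored$score)))
}
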