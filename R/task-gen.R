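#' Task-generator configuration
#'
#' Defines the attribute grids and expected-value (EV) gap calibration of the
#' stimulus generator. The task is designed so that most choices are hard:
#' by default 76% of pairs differ by at most 5 points in EV and 90% by at
#' most 20 points. Pairs are produced by stratified rejection sampling over
#' three |dEV| strata (<= 5, (5, 20], > 20) with mixture weights derived from
#' the two target fractions.
#'
#' @param magnitude_set Allowed win/loss magnitudes (points). Default:
#'   multiples of 10 in 10-200.
#' @param probability_set Allowed win probabilities. Default: 0.05-0.95 grid
#'   in steps of 0.05.
#' @param ev_gap_targets Named vector `c(within_5 = , within_20 = )`: target
#'   fractions of pairs with |dEV| <= 5 and <= 20 points.
#' @return A list of class `task_gen_config`.
#' @export
task_gen_config <- function(magnitude_set = seq(10, 200, by = 10),
                            probability_set = seq(0.05, 0.95, by = 0.05),
                            ev_gap_targets = c(within_5 = 0.76, within_20 = 0.90)) {
  if (length(magnitude_set) == 0 || length(probability_set) == 0) {
    abort("Magnitude and probability sets must be non-empty.")
  }
  if (any(magnitude_set <= 0)) abort("Magnitudes must be positive points.")
  if (any(probability_set < 0 | probability_set > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  f5 <- ev_gap_targets[["within_5"]]
  f20 <- ev_gap_targets[["within_20"]]
  if (f5 < 0 || f20 > 1 || f5 > f20) {
    abort("Infeasible EV-gap targets: need 0 <= within_5 <= within_20 <= 1.")
  }
  structure(list(magnitude_set = magnitude_set,
                 probability_set = probability_set,
                 ev_gap_targets = c(within_5 = f5, within_20 = f20)),
            class = "task_gen_config")
}

draw_raw_options <- function(n, config) {
  tibble(
    p_win = sample(config$probability_set, n, replace = TRUE),
    mag_win = sample(config$magnitude_set, n, replace = TRUE),
    mag_loss = sample(config$magnitude_set, n, replace = TRUE)
  )
}

option_ev <- function(p_win, mag_win, mag_loss) {
  p_win * mag_win - (1 - p_win) * mag_loss
}

#' Generate gamble pairs with calibrated EV gaps
#'
#' Draws `n` left/right option pairs from the configured attribute grids by
#' stratified rejection: each pair's |dEV| stratum (<= 5, (5, 20], > 20) is
#' first drawn from the calibrated mixture, then grid-uniform candidate pairs
#' are rejected until one lands in that stratum. All emitted attributes lie
#' on the grids and the EV-gap fractions match the configured targets up to
#' multinomial sampling error.
#'
#' @param n Number of pairs.
#' @param config A [task_gen_config()].
#' @return A tibble with columns `p_win_left`, `mag_win_left`,
#'   `mag_loss_left`, `p_win_right`, `mag_win_right`, `mag_loss_right`.
#' @examples
#' pairs <- generate_option_pairs(100, task_gen_config())
#' @export
generate_option_pairs <- function(n, config = task_gen_config()) {
  f5 <- config$ev_gap_targets[["within_5"]]
  f20 <- config$ev_gap_targets[["within_20"]]
  mix <- c(f5, f20 - f5, 1 - f20)
  strata_needed <- tabulate(sample.int(3, n, replace = TRUE, prob = mix),
                            nbins = 3)
  out <- vector("list", 3)
  got <- c(0L, 0L, 0L)
  while (any(got < strata_needed)) {
    batch <- max(4L * sum(strata_needed - got), 2000L)
    left <- draw_raw_options(batch, config)
    right <- draw_raw_options(batch, config)
    gap <- abs(option_ev(left$p_win, left$mag_win, left$mag_loss) -
                 option_ev(right$p_win, right$mag_win, right$mag_loss))
    stratum <- 1L + (gap > 5) + (gap > 20)
    cand <- tibble(
      p_win_left = left$p_win, mag_win_left = left$mag_win,
      mag_loss_left = left$mag_loss,
      p_win_right = right$p_win, mag_win_right = right$mag_win,
      mag_loss_right = right$mag_loss
    )
    for (s in 1:3) {
      need <- strata_needed[s] - got[s]
      if (need <= 0L) next
      idx <- which(stratum == s)
      take <- idx[seq_len(min(need, length(idx)))]
      out[[s]] <- bind_rows(out[[s]], cand[take, ])
      got[s] <- got[s] + length(take)
    }
  }
  pairs <- bind_rows(out)
  pairs[sample.int(nrow(pairs)), ]
}
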