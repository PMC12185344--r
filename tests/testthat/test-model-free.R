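hand_trials <- function(df) {
  # fill a minimal but schema-complete trial table from a compact spec
  n <- nrow(df)
  tibble::tibble(
    participant_id = df[["participant_id"]] %||% rep("h1", n),
    day = df[["day"]] %||% rep(1L, n),
    trial = df[["trial"]] %||% seq_len(n),
    p_win_left = df$p_win_left, mag_win_left = df$mag_win_left,
    mag_loss_left = df$mag_loss_left,
    p_win_right = df$p_win_right, mag_win_right = df$mag_win_right,
    mag_loss_right = df$mag_loss_right,
    choice = df$choice, outcome = df$outcome
  )
}
`%||%` <- rlang::`%||%`

test_that("choice curve reduces to direct counting on a hand-made table", {
  # two clearly separated utility-difference levels, two trials each
  tr <- hand_trials(tibble::tibble(
    p_win_left = c(0.9, 0.9, 0.1, 0.1), mag_win_left = 200,
    mag_loss_left = 10,
    p_win_right = c(0.1, 0.1, 0.9, 0.9), mag_win_right = c(10, 10, 200, 200),
    mag_loss_right = c(200, 200, 10, 10),
    choice = c("L", "L", "R", "R"),
    outcome = c(200, 200, 200, 200)
  ))
  cc <- bin_choice_curve(tr, n_bins = 2)
  expect_equal(cc$frac_left, c(0, 1))
  expect_equal(cc$n, c(2L, 2L))
  expect_error(bin_choice_curve(tr, n_bins = 1), "n_bins")
})

test_that("two-bin curve equals the brute-force contingency split", {
  set.seed(50)
  tr <- agent_trials(lambda = 1, gamma = 0, beta = 0.1, n_sessions = 10)
  cc <- bin_choice_curve(tr, n_bins = 2)
  # reward- and loss-utility differences kept separate so boundary ties
  # resolve identically in floating point
  d_rew <- with(tr, p_win_left * mag_win_left - p_win_right * mag_win_right)
  d_loss <- with(tr, (1 - p_win_left) * mag_loss_left -
                   (1 - p_win_right) * mag_loss_right)
  du <- d_rew - d_loss
  med <- median(du)
  lo <- du <= med; hi <- du > med
  # quantile binning puts the boundary at the median
  expect_equal(sort(cc$frac_left),
               sort(c(mean(tr$choice[lo] == "L"),
                      mean(tr$choice[hi] == "L"))))
})

test_that("choice curves are flat at beta = 0 and monotone for greedy agents", {
  set.seed(51)
  flat <- bin_choice_curve(agent_trials(beta = 0, n_sessions = 50))
  expect_true(all(abs(flat$frac_left - 0.5) < 3 * sqrt(0.25 / flat$n)))
  greedy <- bin_choice_curve(agent_trials(beta = 5, n_sessions = 50))
  expect_true(all(diff(greedy$frac_left) >= 0))
})

test_that("dimension slopes track the generative loss weight", {
  set.seed(52)
  sym <- dimension_sensitivity(agent_trials(lambda = 1, beta = 0.2,
                                            n_sessions = 150))$slopes
  expect_lt(abs(sym$win_slope - sym$loss_slope), 0.05)
  asym <- dimension_sensitivity(agent_trials(lambda = 0.5, beta = 0.2,
                                             n_sessions = 150))$slopes
  expect_lt(asym$loss_slope, asym$win_slope)
  blind <- dimension_sensitivity(agent_trials(lambda = 0, beta = 0.2,
                                              n_sessions = 150))$slopes
  expect_lt(abs(blind$loss_slope), 0.05)
})

test_that("outcome-history contrast counts a hand-made table correctly", {
  # 8 post-first trials at extreme loss-utility gaps; lower-loss option is
  # always the left one (d_loss < 0). After wins: 3/4 lower-loss choices;
  # after losses: 1/4.
  base <- tibble::tibble(
    p_win_left = 0.5, mag_win_left = 100, mag_loss_left = 10,
    p_win_right = 0.5, mag_win_right = 100, mag_loss_right = 190
  )
  tr <- dplyr::bind_cols(
    dplyr::bind_rows(replicate(9, base, simplify = FALSE)),
    tibble::tibble(
      participant_id = "h1", day = 1L, trial = 1:9,
      # outcomes set so trials 2-5 follow wins, 6-9 follow losses
      choice = c("L", "L", "L", "L", "R", "L", "R", "R", "R"),
      outcome = c(100, 100, 100, 100, -190, -10, -190, -190, -190)
    )
  )
  # previous-outcome signs: trials 2:5 follow wins, 6:9 follow losses
  oh <- outcome_history_contrast(tr, extreme_fraction = 1)
  expect_equal(oh$contrast, 3 / 4 - 1 / 4)
  expect_false(oh$flagged)
})

test_that("contrast is null for gamma = 0 and signed by gamma", {
  set.seed(53)
  tr0 <- agent_trials(gamma = 0, beta = 0.2, n_sessions = 250)
  oh0 <- outcome_history_contrast(tr0)
  n_eff <- min(oh0$n_after_win, oh0$n_after_loss)
  expect_lt(abs(oh0$contrast), 3 * sqrt(0.5 / n_eff))
  trp <- agent_trials(gamma = 2, beta = 0.3, n_sessions = 250)
  expect_gt(outcome_history_contrast(trp)$contrast, 0.05)
})

test_that("cells without both history conditions are flagged", {
  base <- tibble::tibble(
    p_win_left = 0.5, mag_win_left = 100, mag_loss_left = 10,
    p_win_right = 0.5, mag_win_right = 100, mag_loss_right = 190
  )
  tr <- dplyr::bind_cols(
    dplyr::bind_rows(replicate(3, base, simplify = FALSE)),
    tibble::tibble(participant_id = "h1", day = 1L, trial = 1:3,
                   choice = "L", outcome = c(100, 100, 100))
  )
  expect_warning(oh <- outcome_history_contrast(tr, extreme_fraction = 1),
                 "empty")
  expect_true(oh$flagged)
  expect_true(is.na(oh$contrast))
})

test_that("predictive accuracy brackets chance and certainty", {
  set.seed(54)
  # random agent: accuracy near chance (in-sample fits carry a little
  # optimism from 3 free parameters per 40 trials)
  tr0 <- agent_trials(beta = 0, n_sessions = 25, n_trials = 40)
  fits0 <- fit_sessions(tr0 |> dplyr::mutate(group = "low_mdq",
                                             arm = "none", phase = "none"),
                        seed = 1)
  acc0 <- predictive_accuracy(tr0 |> dplyr::mutate(group = "low_mdq"),
                              fits0)
  expect_lt(abs(acc0$accuracy[acc0$group == "all"] - 0.5), 0.07)
  # near-deterministic agent: accuracy approaches 1
  tr1 <- agent_trials(beta = 5, n_sessions = 25)
  fits1 <- fit_sessions(tr1 |> dplyr::mutate(group = "low_mdq",
                                             arm = "none", phase = "none"),
                        seed = 1)
  acc1 <- predictive_accuracy(tr1 |> dplyr::mutate(group = "low_mdq"),
                              fits1)
  expect_gt(acc1$accuracy[acc1$group == "all"], 0.9)
  # sessions lacking fits are skipped with a warning
  expect_warning(
    predictive_accuracy(tr1 |> dplyr::mutate(group = "low_mdq"),
                        fits1[-1, ]), "skipped")
})
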