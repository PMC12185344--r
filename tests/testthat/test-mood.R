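mk_mood <- function(df) {
  tibble::tibble(
    participant_id = df$participant_id, group = df$group, day = df$day,
    panas_pos = df$panas_pos, panas_neg = df$panas_neg %||% df$panas_pos,
    vas_pre = df$vas_pre %||% 50, vas_post = df$vas_post %||% 50
  )
}
`%||%` <- rlang::`%||%`

test_that("instability is the plain SD of daily scores", {
  mood <- mk_mood(tibble::tibble(
    participant_id = rep(c("a", "b"), each = 3),
    group = "low_mdq", day = rep(1:3, 2),
    panas_pos = c(4, 4, 4, 1, 3, 5)
  ))
  inst <- mood_instability(mood)
  expect_equal(inst$sd_pos[inst$participant_id == "a"], 0)
  expect_equal(inst$sd_pos[inst$participant_id == "b"], 2)
  # invariant to adding a constant to a participant's series
  shifted <- mood |> dplyr::mutate(panas_pos = panas_pos + 10)
  expect_equal(mood_instability(shifted)$sd_pos, inst$sd_pos)
})

test_that("participants with too few days are flagged", {
  mood <- mk_mood(tibble::tibble(
    participant_id = c("a", "a", "a", "b"),
    group = "low_mdq", day = c(1:3, 1), panas_pos = c(1, 2, 3, 5)
  ))
  expect_warning(inst <- mood_instability(mood), "3 mood days")
  expect_true(inst$flagged[inst$participant_id == "b"])
  expect_true(is.na(inst$sd_pos[inst$participant_id == "b"]))
})

test_that("instability gradient is recovered from group-dependent mood noise", {
  set.seed(70)
  cfg <- cohort_config(panas_sd = c(low_mdq = 1, high_mdq = 2, bd = 3))
  sessions <- tidyr::crossing(participant_id = sprintf("m%02d", 1:36),
                              day = 1:20) |>
    dplyr::mutate(group = rep(gradient_levels(), each = 12 * 20),
                  net_outcome = rnorm(dplyr::n(), 0, 300))
  mood <- generate_mood_series(sessions, cfg)
  demo <- sessions |>
    dplyr::distinct(participant_id) |>
    dplyr::mutate(age = rnorm(dplyr::n(), 30, 8),
                  gender = rep(c("F", "M"), 18))
  mi <- mood_instability(mood, demographics = demo)
  for (sc in c("panas_pos", "panas_neg")) {
    r <- mi$summary[mi$summary$term == "g_linear" &
                      mi$summary$scale == sc, ]
    expect_gt(r$estimate, 0)
    expect_true(r$significant)
  }
})

test_that("happiness coupling recovers the generative value and flips sign", {
  set.seed(71)
  cfg <- cohort_config(outcome_coupling = 4, vas_change_sd = 6)
  sessions <- tidyr::crossing(participant_id = sprintf("h%02d", 1:30),
                              day = 1:20) |>
    dplyr::mutate(group = rep(gradient_levels(), each = 10 * 20),
                  net_outcome = rnorm(dplyr::n(), 0, 300))
  mood <- generate_mood_series(sessions, cfg)
  net <- sessions |> dplyr::select(participant_id, day, net_outcome)
  fit <- happiness_outcome_regression(mood, net = net)
  td <- tidy(fit)
  r <- td[td$term == "net_outcome_z", ]
  expect_true(r$ci_lower <= 4 && 4 <= r$ci_upper)
  expect_true(r$significant)
  # negating all outcomes flips the coupling's sign
  fit_neg <- happiness_outcome_regression(
    mood, net = net |> dplyr::mutate(net_outcome = -net_outcome))
  td_neg <- tidy(fit_neg)
  expect_equal(td_neg$estimate[td_neg$term == "net_outcome_z"],
               -r$estimate, tolerance = 1e-6)
})

test_that("degenerate happiness designs are rejected", {
  mood <- mk_mood(tibble::tibble(
    participant_id = rep("a", 3), group = "low_mdq", day = 1:3,
    panas_pos = 3, vas_pre = 50, vas_post = 55
  ))
  net_const <- tibble::tibble(participant_id = "a", day = 1:3,
                              net_outcome = 100)
  expect_error(happiness_outcome_regression(mood, net = net_const),
               "unidentifiable")
  mood_na <- mood |> dplyr::mutate(vas_post = NA_real_)
  expect_error(happiness_outcome_regression(
    mood_na, net = net_const |> dplyr::mutate(net_outcome = c(1, 2, 3))),
    "No sessions")
})

test_that("mood-noisiness coupling recovers the generative interaction", {
  set.seed(72)
  # build session-wise log beta directly from the generator's truth layer:
  # positive mood raises effective beta in the patient group only
  cfg <- cohort_config(
    group_sizes = c(low_mdq = 12, high_mdq = 12, bd_lithium = 6,
                    bd_placebo = 6),
    days_volunteer = 20, days_baseline = 6, days_post = 14,
    mood_noisiness_coupling = c(low_mdq = 0, high_mdq = 0, bd = 0.5),
    within_sd = c(lambda = 0.3, gamma = 0.2, log_beta = 0.15)
  )
  truth <- simulate_session_params(cfg)
  fits <- truth |>
    dplyr::transmute(participant_id, day, log_beta_mean = log_beta)
  mood <- truth |>
    dplyr::transmute(participant_id, group = as.character(group), day,
                     panas_pos, panas_neg = panas_pos, vas_pre = 50,
                     vas_post = 50)
  mc <- mood_noisiness_coupling(fits, mood)
  td <- tidy(mc$daily)
  # BD sits at the high end of the gradient: coupling only there means a
  # positive panas x gradient interaction
  r <- td[td$term == "panas_x_gradient", ]
  expect_gt(r$estimate, 0)
  expect_true(r$significant)
})

test_that("null mood-noisiness coupling stays null", {
  set.seed(73)
  cfg <- cohort_config(
    group_sizes = c(low_mdq = 10, high_mdq = 10, bd_lithium = 5,
                    bd_placebo = 5),
    days_volunteer = 15, days_baseline = 5, days_post = 10,
    mood_noisiness_coupling = c(low_mdq = 0, high_mdq = 0, bd = 0)
  )
  truth <- simulate_session_params(cfg)
  fits <- truth |>
    dplyr::transmute(participant_id, day, log_beta_mean = log_beta)
  mood <- truth |>
    dplyr::transmute(participant_id, group = as.character(group), day,
                     panas_pos, panas_neg = panas_pos, vas_pre = 50,
                     vas_post = 50)
  td <- tidy(mood_noisiness_coupling(fits, mood)$daily)
  r <- td[td$term == "panas_x_gradient", ]
  expect_false(r$significant)
})

test_that("single-day participants are excluded with a warning", {
  set.seed(74)
  ids <- c(rep("a", 4), "b", rep("c", 4), rep("d", 4))
  fits <- tibble::tibble(participant_id = ids,
                         day = c(1:4, 1, 1:4, 1:4),
                         log_beta_mean = rnorm(13, -2, 0.3))
  mood <- mk_mood(tibble::tibble(
    participant_id = ids,
    group = rep(c("low_mdq", "low_mdq", "high_mdq", "high_mdq"),
                c(4, 1, 4, 4)),
    day = c(1:4, 1, 1:4, 1:4), panas_pos = rnorm(13, 30, 2)
  ))
  expect_warning(mood_noisiness_coupling(fits, mood), "single mood day")
})
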