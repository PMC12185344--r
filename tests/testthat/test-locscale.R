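test_that("gradient codes are the closed-form orthonormal polynomials", {
  g3 <- gradient_codes(3)
  expect_equal(g3[, "linear"], c(-1, 0, 1) / sqrt(2))
  expect_equal(g3[, "quadratic"], c(1, -2, 1) / sqrt(6))
  g2 <- gradient_codes(2)
  expect_equal(g2[, "linear"], c(-1, 1) / sqrt(2))
  for (k in 2:6) {
    g <- gradient_codes(k)
    expect_equal(unname(colSums(g)), rep(0, k - 1), tolerance = 1e-12)
    expect_equal(crossprod(g), diag(k - 1), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_error(gradient_codes(1), "at least 2")
})

sim_sessionwise <- function(group_means, n_per_group = 12, n_days = 10,
                            sd_between = 0.3, sd_within = 0.4,
                            group_sigma = NULL) {
  k <- length(group_means)
  groups <- gradient_levels()[seq_len(k)]
  purrr::imap(setNames(group_means, groups), function(mu, g) {
    tidyr::crossing(pid = seq_len(n_per_group), day = seq_len(n_days)) |>
      dplyr::mutate(
        participant_id = sprintf("%s_%02d", g, pid), group = g,
        age = rnorm(dplyr::n(), 30, 8),
        gender = sample(c("F", "M"), dplyr::n(), replace = TRUE)
      ) |>
      dplyr::group_by(participant_id) |>
      dplyr::mutate(u = rnorm(1, 0, sd_between)) |>
      dplyr::ungroup() |>
      dplyr::mutate(y = mu + u + rnorm(
        dplyr::n(), 0,
        if (is.null(group_sigma)) sd_within else group_sigma[[g]]))
  }) |> dplyr::bind_rows() |> dplyr::select(-pid)
}

test_that("a simulated monotone group shift yields a signed linear gradient", {
  set.seed(60)
  dat <- sim_sessionwise(c(low_mdq = 0.6, high_mdq = 0.3, bd = 0.0),
                         n_per_group = 15)
  r <- g_linear_row(fit_location_scale(dat, "y"))
  expect_lt(r$estimate, 0)
  expect_true(r$significant)
})

test_that("the gradient depends only on group order, not labels", {
  set.seed(61)
  dat <- sim_sessionwise(c(low_mdq = 0.5, high_mdq = 0.25, bd = 0.0))
  r1 <- g_linear_row(fit_location_scale(dat, "y"))
  relab <- dat |>
    dplyr::mutate(group = factor(
      dplyr::recode(group, low_mdq = "alpha", high_mdq = "beta",
                    bd = "gamma"),
      levels = c("alpha", "beta", "gamma"), ordered = TRUE))
  r2 <- g_linear_row(fit_location_scale(relab, "y"))
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-4)
})

test_that("without dispersion and random effects the engine matches least squares", {
  set.seed(62)
  dat <- sim_sessionwise(c(low_mdq = 0.4, high_mdq = 0.2, bd = 0.0),
                         n_per_group = 4, n_days = 1, sd_between = 0,
                         sd_within = 0.3)
  # participant-level regression (one row each, no random effects)
  fit <- moodgamble:::gradient_regression(dat |> dplyr::mutate(day = 1), "y")
  td <- tidy(fit)
  prep <- moodgamble:::prepare_covariates(dat |> dplyr::mutate(day = 1))
  ls <- lm(y ~ g_linear + g_quadratic + age_z + gender_c, data = prep)
  for (term in c("g_linear", "g_quadratic", "age_z", "gender_c")) {
    expect_equal(td$estimate[td$term == term & td$submodel == "mean"],
                 unname(coef(ls)[term]), tolerance = 0.02)
  }
})

test_that("the dispersion submodel detects group differences in variability", {
  set.seed(63)
  dat <- sim_sessionwise(c(low_mdq = 0, high_mdq = 0, bd = 0),
                         n_per_group = 15, n_days = 15, sd_between = 0.2,
                         group_sigma = list(low_mdq = 1, high_mdq = 2,
                                            bd = 3))
  td <- tidy(fit_location_scale(dat, "y"))
  r <- td[td$term == "g_linear" & td$submodel == "scale", ]
  expect_gt(r$estimate, 0)
  expect_true(r$significant)
})

test_that("unidentifiable designs are rejected", {
  set.seed(64)
  dat <- sim_sessionwise(c(low_mdq = 0, high_mdq = 0, bd = 0),
                         n_per_group = 1)
  expect_error(fit_location_scale(dat, "y"), "2 participants")
  expect_error(fit_location_scale(dplyr::select(dat, -age), "y"), "age")
})

sim_drug <- function(effect = 0, n_arm = 8, pre = 4, post = 8) {
  tidyr::crossing(arm = c("lithium", "placebo"), pid = seq_len(n_arm),
                  day = seq_len(pre + post)) |>
    dplyr::mutate(
      participant_id = paste0(arm, "_", pid),
      phase = ifelse(day <= pre, "pre", "post"),
      group = "bd", age = 30, gender = rep(c("F", "M"),
                                           length.out = dplyr::n())
    ) |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(u = rnorm(1, 0, 0.3)) |>
    dplyr::ungroup() |>
    dplyr::mutate(y = -2 + u +
                    effect * (arm == "lithium") * (phase == "post") +
                    rnorm(dplyr::n(), 0, 0.3))
}

test_that("drug-by-time interaction recovers a simulated treatment shift", {
  set.seed(65)
  dat <- sim_drug(effect = 0.5)
  td <- tidy(drug_time_interaction(dat, "y"))
  r <- td[td$term == "drug_x_phase", ]
  expect_equal(r$estimate, 0.5, tolerance = 0.25)
  expect_true(r$significant)
  # permuting arm labels destroys the effect
  perm <- dat |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(arm = sample(c("lithium", "placebo"), 1)) |>
    dplyr::ungroup()
  td_p <- tidy(drug_time_interaction(perm, "y"))
  expect_lt(abs(td_p$estimate[td_p$term == "drug_x_phase"]),
            abs(r$estimate))
})

test_that("a missing phase in either arm is an error", {
  set.seed(66)
  dat <- sim_drug(effect = 0) |> dplyr::filter(!(arm == "placebo" &
                                                   phase == "post"))
  expect_error(drug_time_interaction(dat, "y"), "pre and post")
})
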