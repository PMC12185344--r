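test_that("option utilities follow the loss-weighted expected-value rule", {
  # gamma = 0 reduces to plain expected utility
  expect_equal(option_utility(0.7, 100, 50, lambda = 1, gamma = 0,
                              prev_sign = -1), 55)
  # history term scales the loss weight after a win
  expect_equal(option_utility(0.7, 100, 50, lambda = 1, gamma = 0.2,
                              prev_sign = 1), 52)
  # sure win: the loss term vanishes
  expect_equal(option_utility(1, 123, 77, lambda = 2.5, gamma = -1,
                              prev_sign = 1), 123)
  expect_error(option_utility(0.5, 10, 10, 1, prev_sign = 0.5), "prev_sign")
  expect_error(option_utility(1.2, 10, 10, 1), "p_win")
})

test_that("softmax choice rule is symmetric, bounded and overflow-safe", {
  expect_equal(choice_prob_left(42, 42, 3), 0.5)
  expect_equal(choice_prob_left(-500, 900, 0), 0.5)
  expect_equal(choice_prob_left(10, 0, 0.1), 1 / (1 + exp(-1)))
  # extreme utility gaps stay finite and inside [0, 1]
  p <- choice_prob_left(1e6, -1e6, 10)
  expect_true(is.finite(p) && p <= 1 && p >= 0)
  expect_error(choice_prob_left(1, 0, -0.1), "non-negative")
})

test_that("complementarity and monotonicity hold on random inputs", {
  set.seed(41)
  u1 <- runif(200, -200, 200); u2 <- runif(200, -200, 200)
  b <- runif(200, 0, 1)
  expect_equal(choice_prob_left(u1, u2, b) + choice_prob_left(u2, u1, b),
               rep(1, 200))
  # increasing lambda strictly decreases utility when a loss is possible
  for (i in 1:50) {
    p <- runif(1, 0.05, 0.95); w <- sample(10:200, 1); l <- sample(10:200, 1)
    lam <- sort(runif(2, -1, 3))
    expect_lt(option_utility(p, w, l, lam[2]), option_utility(p, w, l, lam[1]))
  }
})

test_that("session log-likelihood matches the brute-force per-trial oracle", {
  set.seed(42)
  for (i in 1:25) {
    lam <- rnorm(1, 1, 0.5); gam <- rnorm(1, 0, 0.5)
    bet <- exp(rnorm(1, log(0.1), 1))
    s <- simulate_session(lam, gam, bet, n_trials = sample(5:30, 1))
    expect_equal(session_log_likelihood(s, lam, gam, bet),
                 brute_force_loglik(s, lam, gam, bet), tolerance = 1e-12)
  }
})

test_that("log-likelihood limits and invariances", {
  set.seed(7)
  s <- simulate_session(1, 0.3, 0.1, 20)
  # beta = 0: every choice has probability 1/2
  expect_equal(session_log_likelihood(s, 1, 0.3, 0), 20 * log(0.5))
  # with gamma = 0 the history chain is irrelevant
  s_shuf <- s[sample(nrow(s)), ]
  s_shuf$trial <- seq_len(nrow(s_shuf))  # breaks the outcome chain
  expect_equal(session_log_likelihood(s, 1, 0, 0.2),
               sum(log(pmax(ifelse(
                 s$choice == "L",
                 choice_prob_left(
                   option_utility(s$p_win_left, s$mag_win_left,
                                  s$mag_loss_left, 1),
                   option_utility(s$p_win_right, s$mag_win_right,
                                  s$mag_loss_right, 1), 0.2),
                 1 - choice_prob_left(
                   option_utility(s$p_win_left, s$mag_win_left,
                                  s$mag_loss_left, 1),
                   option_utility(s$p_win_right, s$mag_win_right,
                                  s$mag_loss_right, 1), 0.2)), 1e-12))))
  # joint left/right relabelling leaves the likelihood unchanged
  flipped <- s |>
    dplyr::rename(p_win_left = p_win_right, p_win_right = p_win_left,
                  mag_win_left = mag_win_right, mag_win_right = mag_win_left,
                  mag_loss_left = mag_loss_right,
                  mag_loss_right = mag_loss_left) |>
    dplyr::mutate(choice = ifelse(choice == "L", "R", "L"))
  expect_equal(session_log_likelihood(flipped, 1, 0.3, 0.2),
               session_log_likelihood(s, 1, 0.3, 0.2))
})

test_that("data-integrity errors are raised", {
  s <- simulate_session(1, 0, 0.1, 10)
  expect_error(session_log_likelihood(s[0, ], 1, 0, 0.1), "Empty")
  bad <- s
  bad$prev_sign <- rev(bad$prev_sign)
  if (!isTRUE(all.equal(bad$prev_sign, s$prev_sign))) {
    expect_error(session_log_likelihood(bad, 1, 0, 0.1), "disagrees")
  }
})

test_that("simulated choices follow the softmax closed form", {
  set.seed(8)
  left <- list(p_win = 1, mag_win = 60, mag_loss = 10)
  right <- list(p_win = 0.5, mag_win = 100, mag_loss = 100)
  # u_left - u_right = 60 - 0 = 60; beta 10: left essentially always chosen
  res <- replicate(300, simulate_trial(left, right, 1, 0, 10)$choice)
  expect_true(all(res == "L"))
  # chosen sure-win option always pays its win magnitude
  out <- replicate(50, simulate_trial(left, right, 1, 0, 10)$outcome)
  expect_true(all(out == 60))
  # Monte-Carlo vs closed form at beta = 0.1, du = 10
  l2 <- list(p_win = 0.5, mag_win = 120, mag_loss = 100)
  r2 <- list(p_win = 0.5, mag_win = 100, mag_loss = 100)
  ch <- replicate(10000, simulate_trial(l2, r2, 1, 0, 0.1)$choice)
  p_hat <- mean(ch == "L")
  p_true <- 1 / (1 + exp(-1))
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 3 * se)
})
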