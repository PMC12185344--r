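#' Mood instability
#'
#' Mood instability is the within-participant standard deviation of the
#' daily PANAS scores (the study's stated measure; model-based volatility is
#' out of scope). Participants with fewer than 3 mood days are flagged and
#' get `NA`. If a demographics table is supplied, the gradient effect on the
#' instability of each scale is tested with a participant-level Bayesian
#' regression (`sd ~ 1 + gradient + age + gender`), since instability is one
#' number per participant.
#'
#' @param mood Mood table (`participant_id`, `group`, `day`, `panas_pos`,
#'   `panas_neg`, ...).
#' @param demographics Optional tibble with `participant_id`, `age`,
#'   `gender`.
#' @return If `demographics` is `NULL`, a tibble of per-participant SDs.
#'   Otherwise a list of class `mood_instability` with `instability` and a
#'   combined coefficient `summary` for both scales.
#' @export
mood_instability <- function(mood, demographics = NULL) {
  inst <- mood |>
    group_by(.data$participant_id, group = as.character(.data$group)) |>
    summarise(n_days = dplyr::n_distinct(.data$day),
              sd_pos = sd(.data$panas_pos), sd_neg = sd(.data$panas_neg),
              .groups = "drop") |>
    mutate(flagged = .data$n_days < 3,
           sd_pos = ifelse(.data$flagged, NA_real_, .data$sd_pos),
           sd_neg = ifelse(.data$flagged, NA_real_, .data$sd_neg))
  if (any(inst$flagged)) {
    warn("Participants with < 3 mood days flagged; instability set to NA.")
  }
  if (is.null(demographics)) return(inst)
  dat <- inst |>
    filter(!.data$flagged) |>
    left_join(demographics |> select("participant_id", "age", "gender"),
              by = "participant_id") |>
    mutate(day = 1)  # participant-level: day is a dummy for the helpers
  fits <- purrr::map(c(panas_pos = "sd_pos", panas_neg = "sd_neg"),
                     function(col) gradient_regression(dat, col))
  summary <- purrr::imap(fits, \(f, nm) f$summary |> mutate(scale = nm)) |>
    bind_rows()
  structure(list(instability = inst, summary = summary, fits = fits),
            class = "mood_instability")
}

#' @export
print.mood_instability <- function(x, ...) {
  cat("<mood_instability>", nrow(x$instability), "participants\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

# Participant-level Bayesian regression (no random effects): used where the
# outcome is one value per participant.
gradient_regression <- function(data, outcome, extra_terms = NULL) {
  data <- prepare_covariates(data) |> filter(!is.na(.data[[outcome]]))
  k <- nlevels(data$group)
  grad_terms <- if (k >= 3) c("g_linear", "g_quadratic") else "g_linear"
  mean_terms <- c("(Intercept)", grad_terms, "age_z", "gender_c",
                  extra_terms)
  X <- cbind(1, as.matrix(data[, mean_terms[-1]]))
  eng <- locscale_engine(data[[outcome]], X, matrix(1, nrow(data), 1))
  new_locscale_fit(eng, mean_terms, "(Intercept)", outcome, nrow(data),
                   nrow(data))
}

#' Happiness change and session outcomes
#'
#' Across sessions, the post-minus-pre happiness VAS change is regressed on
#' the session's summed net outcome (standardised across the included
#' sessions), with a gradient main effect and a gradient-by-outcome
#' interaction, and random participant intercepts. The `net_outcome_z`
#' coefficient is the happiness-outcome coupling (VAS points per SD of net
#' outcome); `net_x_gradient` asks whether the coupling changes along the
#' bipolar gradient.
#'
#' @param mood Mood table with `vas_pre` and `vas_post`.
#' @param trials Trial table used to sum each session's realized outcomes
#'   (alternatively supply `net` directly).
#' @param net Optional tibble `participant_id`, `day`, `net_outcome`
#'   overriding `trials`.
#' @return A `locscale_fit`.
#' @export
happiness_outcome_regression <- function(mood, trials = NULL, net = NULL) {
  if (is.null(net)) {
    if (is.null(trials)) abort("Supply `trials` or `net`.")
    net <- trials |>
      group_by(.data$participant_id, .data$day) |>
      summarise(net_outcome = sum(.data$outcome), .groups = "drop")
  }
  dat <- mood |>
    left_join(net, by = c("participant_id", "day")) |>
    filter(!is.na(.data$net_outcome)) |>
    mutate(dvas = .data$vas_post - .data$vas_pre) |>
    filter(!is.na(.data$dvas))
  if (nrow(dat) == 0) abort("No sessions with both VAS ratings and outcomes.")
  if (sd(dat$net_outcome) == 0) {
    abort("Net outcomes are identical across sessions: the happiness-outcome coupling is unidentifiable.")
  }
  if (!is.ordered(dat$group)) {
    lv <- intersect(gradient_levels(), unique(as.character(dat$group)))
    dat$group <- factor(as.character(dat$group), levels = lv, ordered = TRUE)
  }
  k <- nlevels(dat$group)
  dat <- dat |>
    mutate(net_outcome_z = as.numeric(scale(.data$net_outcome)))
  if (k >= 2) {
    codes <- gradient_codes(k)
    gi <- as.integer(dat$group)
    dat <- dat |>
      mutate(g_linear = codes[gi, "linear"],
             net_x_gradient = .data$net_outcome_z * .data$g_linear)
    terms <- c("(Intercept)", "net_outcome_z", "g_linear", "net_x_gradient")
  } else {
    terms <- c("(Intercept)", "net_outcome_z")
  }
  X <- cbind(1, as.matrix(dat[, terms[-1]]))
  eng <- locscale_engine(dat$dvas, X, matrix(1, nrow(dat), 1),
                         id = dat$participant_id)
  new_locscale_fit(eng, terms, "(Intercept)", "dvas", nrow(dat),
                   dplyr::n_distinct(dat$participant_id))
}

#' Mood and choice noisiness
#'
#' Two linked analyses of how mood relates to the randomness of choices
#' (inversely, the session's fitted `log beta`):
#' \itemize{
#'   \item daily: session `log beta` regressed on the same day's positive
#'     PANAS (standardised within participant), its interaction with the
#'     gradient (`panas_x_gradient` — does mood bite harder along the
#'     gradient?), and random participant intercepts;
#'   \item between participants: mean `log beta` regressed on positive-PANAS
#'     instability (`sd_pos`) — more unstable mood, more random choices.
#' }
#' Participants with a single mood day cannot contribute a within-person
#' standardised score and are excluded with a warning.
#'
#' @param fits Session-fits table from [fit_sessions()] (needs
#'   `log_beta_mean`).
#' @param mood Mood table.
#' @return A list of class `mood_coupling` with `daily` and `between`
#'   `locscale_fit`s.
#' @export
mood_noisiness_coupling <- function(fits, mood) {
  dat <- fits |>
    select("participant_id", "day", "log_beta_mean") |>
    left_join(mood, by = c("participant_id", "day")) |>
    filter(!is.na(.data$panas_pos))
  n_days <- dat |> dplyr::count(.data$participant_id)
  single <- n_days$participant_id[n_days$n < 2]
  if (length(single) > 0) {
    warn(sprintf("%d participant(s) with a single mood day excluded.",
                 length(single)))
    dat <- dat |> filter(!.data$participant_id %in% single)
  }
  if (!is.ordered(dat$group)) {
    lv <- intersect(gradient_levels(), unique(as.character(dat$group)))
    dat$group <- factor(as.character(dat$group), levels = lv, ordered = TRUE)
  }
  dat <- dat |>
    group_by(.data$participant_id) |>
    mutate(panas_z = (.data$panas_pos - mean(.data$panas_pos)) /
             ifelse(sd(.data$panas_pos) > 0, sd(.data$panas_pos), 1)) |>
    ungroup()
  k <- nlevels(dat$group)
  if (k >= 2) {
    codes <- gradient_codes(k)
    gi <- as.integer(dat$group)
    dat <- dat |>
      mutate(g_linear = codes[gi, "linear"],
             panas_x_gradient = .data$panas_z * .data$g_linear)
    terms <- c("(Intercept)", "panas_z", "g_linear", "panas_x_gradient")
  } else {
    terms <- c("(Intercept)", "panas_z")
  }
  X <- cbind(1, as.matrix(dat[, terms[-1]]))
  eng <- locscale_engine(dat$log_beta_mean, X, matrix(1, nrow(dat), 1),
                         id = dat$participant_id)
  daily <- new_locscale_fit(eng, terms, "(Intercept)", "log_beta",
                            nrow(dat),
                            dplyr::n_distinct(dat$participant_id))
  between_dat <- dat |>
    group_by(.data$participant_id, group = as.character(.data$group)) |>
    summarise(mean_log_beta = mean(.data$log_beta_mean),
              sd_pos = sd(.data$panas_pos), .groups = "drop") |>
    filter(!is.na(.data$sd_pos), .data$sd_pos > 0) |>
    mutate(sd_pos_z = as.numeric(scale(.data$sd_pos)))
  Xb <- cbind(1, sd_pos_z = between_dat$sd_pos_z)
  engb <- locscale_engine(between_dat$mean_log_beta, Xb,
                          matrix(1, nrow(between_dat), 1))
  between <- new_locscale_fit(engb, c("(Intercept)", "sd_pos_z"),
                              "(Intercept)", "mean_log_beta",
                              nrow(between_dat), nrow(between_dat))
  structure(list(daily = daily, between = between), class = "mood_coupling")
}

#' @export
print.mood_coupling <- function(x, ...) {
  cat("<mood_coupling>\n-- daily --\n")
  print(x$daily)
  cat("-- between participants --\n")
  print(x$between)
  invisible(x)
}
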