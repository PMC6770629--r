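# Within-person first-difference crossover analysis.
#
# Each participant's treatment-shop outcome is differenced against their
# control shop; the differences are regressed on an NS dummy by OLS with
# cluster-robust (participant-level) errors. The intercept alpha is the
# MTL-vs-Control effect, beta_ns the incremental NS-over-MTL effect, and
# alpha + beta_ns the NS-vs-Control contrast.

#' Build within-person first differences
#'
#' For every participant with a scored Control shop, emits one observation
#' per treatment shop: the treatment-minus-control outcome difference with
#' an indicator for the NS condition. Participants without a control shop
#' (or whose relevant outcomes are missing) contribute no observations, so
#' a cohort where 145 participants complete all three shops and 2 complete
#' control plus one treatment yields 292 observations from 147
#' participants.
#'
#' Moderator indicators are attached for the treatment shop: `hungry` and
#' `happy` are median splits of the post-shop survey values (at or above
#' the cohort median maps to 1), and `high_income` / `high_education` come
#' from the participant table when supplied.
#'
#' @param summaries Per-shop outcome tibble from [score_baskets()] (must
#'   carry `participant_id`, `shop_index`, `condition` and the outcome).
#' @param outcome Name of the outcome column to difference.
#' @param participants Optional participant tibble supplying
#'   `high_income` and `high_education`.
#' @return A tibble with columns `participant_id`, `shop_index`,
#'   `condition`, `ns_dummy`, `delta`, and the moderator indicators.
#' @export
build_differences <- function(summaries, outcome, participants = NULL) {
  summaries <- tibble::as_tibble(summaries)
  if (!outcome %in% names(summaries)) {
    rlang::abort(paste0("unknown outcome: ", outcome),
                 class = "nutricart_data_error")
  }
  dup <- summaries |>
    dplyr::count(.data$participant_id, .data$condition) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(paste0("duplicate condition within participant(s): ",
                        paste(unique(dup$participant_id), collapse = ", ")),
                 class = "nutricart_data_error")
  }
  y <- summaries[[outcome]]
  keep <- !is.na(y)
  summaries <- summaries[keep, ]
  y <- y[keep]

  has_survey <- all(c("post_shop_mood", "post_shop_hunger") %in% names(summaries))
  if (has_survey) {
    mood_med <- stats::median(summaries$post_shop_mood, na.rm = TRUE)
    hunger_med <- stats::median(summaries$post_shop_hunger, na.rm = TRUE)
  }
  control <- summaries |>
    dplyr::filter(.data$condition == "Control") |>
    dplyr::select("participant_id", control_y = dplyr::all_of(outcome))
  out <- summaries |>
    dplyr::filter(.data$condition != "Control") |>
    dplyr::inner_join(control, by = "participant_id") |>
    dplyr::mutate(
      ns_dummy = as.integer(.data$condition == "NS"),
      delta = .data[[outcome]] - .data$control_y)
  if (has_survey) {
    out <- dplyr::mutate(
      out,
      hungry = as.integer(.data$post_shop_hunger >= hunger_med),
      happy = as.integer(.data$post_shop_mood >= mood_med))
  }
  out <- dplyr::select(out, "participant_id", "shop_index", "condition",
                       "ns_dummy", "delta",
                       dplyr::any_of(c("hungry", "happy")))
  if (!is.null(participants)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(tibble::as_tibble(participants), "participant_id",
                    dplyr::any_of(c("high_income", "high_education"))),
      by = "participant_id")
  }
  out
}

cluster_vcov <- function(fit, cluster, cadjust = TRUE) {
  # Stata-style CR1: HC1 finite-sample factor times G/(G-1)
  sandwich::vcovCL(fit, cluster = cluster, type = "HC1", cadjust = cadjust)
}

contrast_row <- function(term, L, coefs, V, df, sided) {
  est <- drop(L %*% coefs)
  se <- sqrt(drop(t(L) %*% V %*% L))
  tval <- est / se
  p <- if (sided == "two") 2 * stats::pt(-abs(tval), df)
       else stats::pt(tval, df, lower.tail = FALSE)
  tibble::tibble(term = term, estimate = est, std.error = se,
                 statistic = tval, p.value = p)
}

new_fd_fit <- function(effects, fit, vcov, cluster, sided, moderator = NULL) {
  structure(
    list(effects = effects, model = fit, vcov = vcov,
         n_participants = length(unique(cluster)),
         n_observations = length(cluster),
         df = length(unique(cluster)) - length(stats::coef(fit)),
         sided = sided, moderator = moderator),
    class = "fd_fit")
}

#' Fit the first-difference crossover model
#'
#' OLS of the within-person difference on an intercept and the NS dummy,
#' with cluster-robust (CR1 sandwich) covariance grouped by participant.
#' Reports the three contrasts of interest: `alpha` (MTL vs Control),
#' `beta_ns` (NS over MTL), and their sum `alpha_plus_beta` (NS vs
#' Control). P-values use a t reference with degrees of freedom equal to
#' the number of clusters minus the number of coefficients.
#'
#' @param differences Output of [build_differences()].
#' @param sided `"two"` (default, matching conventional reporting) or
#'   `"greater"` for the one-sided improvement tests.
#' @param df Degrees of freedom for p-values; default clusters minus
#'   parameters.
#' @param cadjust Apply the G/(G-1) cluster correction (default TRUE).
#' @return An object of class `fd_fit`; see [tidy.fd_fit()],
#'   [glance.fd_fit()], [autoplot.fd_fit()].
#' @export
fit_first_difference <- function(differences, sided = c("two", "greater"),
                                 df = NULL, cadjust = TRUE) {
  sided <- match.arg(sided)
  if (nrow(differences) < 2) {
    rlang::abort("need at least two difference observations",
                 class = "nutricart_data_error")
  }
  if (dplyr::n_distinct(differences$ns_dummy) < 2) {
    rlang::abort("both MTL and NS observations are required (rank deficiency)",
                 class = "nutricart_rank_error")
  }
  fit <- stats::lm(delta ~ ns_dummy, data = differences)
  V <- cluster_vcov(fit, differences$participant_id, cadjust)
  G <- dplyr::n_distinct(differences$participant_id)
  if (is.null(df)) df <- G - length(stats::coef(fit))
  coefs <- stats::coef(fit)
  eff <- dplyr::bind_rows(
    contrast_row("alpha", c(1, 0), coefs, V, df, sided),
    contrast_row("beta_ns", c(0, 1), coefs, V, df, sided),
    contrast_row("alpha_plus_beta", c(1, 1), coefs, V, df, sided))
  new_fd_fit(eff, fit, V, differences$participant_id, sided)
}

#' Fit the moderator interaction model
#'
#' OLS of the difference on the NS dummy, a binary moderator, and their
#' interaction, with cluster-robust errors. Besides the base contrasts it
#' reports `beta_m` (the moderator's shift of the MTL effect), `beta_int`
#' (the interaction), and `beta_m_plus_int` (the moderator's shift of the
#' NS effect).
#'
#' @inheritParams fit_first_difference
#' @param moderator Name of a binary 0/1 column of `differences`
#'   (`hungry`, `happy`, `high_income`, `high_education`, or any median
#'   split).
#' @return An `fd_fit` object.
#' @export
fit_moderator <- function(differences, moderator,
                          sided = c("two", "greater"), df = NULL,
                          cadjust = TRUE) {
  sided <- match.arg(sided)
  if (!moderator %in% names(differences)) {
    rlang::abort(paste0("no such moderator column: ", moderator),
                 class = "nutricart_data_error")
  }
  m <- differences[[moderator]]
  if (dplyr::n_distinct(m) < 2) {
    rlang::abort("moderator is constant (rank deficiency)",
                 class = "nutricart_rank_error")
  }
  dat <- dplyr::mutate(differences, .m = m)
  fit <- stats::lm(delta ~ ns_dummy * .m, data = dat)
  V <- cluster_vcov(fit, dat$participant_id, cadjust)
  G <- dplyr::n_distinct(dat$participant_id)
  if (is.null(df)) df <- G - length(stats::coef(fit))
  coefs <- stats::coef(fit)  # (Intercept), ns_dummy, .m, ns_dummy:.m
  eff <- dplyr::bind_rows(
    contrast_row("alpha", c(1, 0, 0, 0), coefs, V, df, sided),
    contrast_row("beta_ns", c(0, 1, 0, 0), coefs, V, df, sided),
    contrast_row("alpha_plus_beta", c(1, 1, 0, 0), coefs, V, df, sided),
    contrast_row("beta_m", c(0, 0, 1, 0), coefs, V, df, sided),
    contrast_row("beta_int", c(0, 0, 0, 1), coefs, V, df, sided),
    contrast_row("beta_m_plus_int", c(0, 0, 1, 1), coefs, V, df, sided))
  new_fd_fit(eff, fit, V, dat$participant_id, sided, moderator = moderator)
}

#' @export
print.fd_fit <- function(x, ...) {
  cat("First-difference crossover fit",
      if (!is.null(x$moderator)) paste0(" (moderator: ", x$moderator, ")"),
      "\n", sep = "")
  cat(sprintf("  n = %d participants, N = %d observations, %s-sided p-values\n",
              x$n_participants, x$n_observations, x$sided))
  print(x$effects)
  invisible(x)
}

#' Tidy a first-difference fit
#'
#' @param x An `fd_fit` object.
#' @param ... Unused.
#' @return The contrast table: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.fd_fit <- function(x, ...) x$effects

#' Fit-level summary of a first-difference fit
#'
#' @param x An `fd_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_participants`, `n_observations`, `df`,
#'   `r.squared`, `sigma`.
#' @exportS3Method generics::glance
glance.fd_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(n_participants = x$n_participants,
                 n_observations = x$n_observations,
                 df = x$df, r.squared = s$r.squared, sigma = s$sigma)
}

#' Coefficient plot of a first-difference fit
#'
#' @param object An `fd_fit` object.
#' @param conf_level Confidence level for the interval whiskers.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fd_fit <- function(object, conf_level = 0.95, ...) {
  crit <- stats::qt(1 - (1 - conf_level) / 2, object$df)
  dat <- dplyr::mutate(
    object$effects,
    lo = .data$estimate - crit * .data$std.error,
    hi = .data$estimate + crit * .data$std.error,
    term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = "Estimated effect", y = NULL) +
    ggplot2::theme_minimal()
}

.stratum_outcomes <- c(
  "avg_nutriscore", "total_energy_kcal", "total_sugar_g", "total_fat_g",
  "total_satfat_g", "total_sodium_mg", "total_fiber_g", "total_protein_g",
  "mean_energy_kcal_serving", "mean_sugar_g_serving", "mean_fat_g_serving",
  "mean_satfat_g_serving", "mean_sodium_mg_serving", "mean_fiber_g_serving",
  "mean_protein_g_serving", "total_spend_sgd", "kcal_per_dollar")

#' Run the crossover analysis over a full orders table
#'
#' Scores every basket, builds first differences and fits the crossover
#' model for each requested outcome, optionally restricted to food or
#' beverage lines. The modified AHEI is a whole-basket composite spanning
#' food and drink groups, so it is only available for `stratum = "all"`;
#' requesting it in a stratified run is an error. Shops with no lines in
#' the stratum get missing outcomes and drop out of the differences.
#'
#' @param orders,catalog,participants As in [score_baskets()].
#' @param outcomes Character vector of outcome names; default is the full
#'   battery (plus `modified_ahei` when `stratum = "all"`).
#' @param stratum `"all"`, `"foods"` or `"beverages"`.
#' @param ... Passed to [fit_first_difference()].
#' @return A tibble of contrast rows with leading columns `stratum`,
#'   `outcome`, `n_participants`, `n_observations`.
#' @export
run_crossover <- function(orders, catalog, participants, outcomes = NULL,
                          stratum = c("all", "foods", "beverages"), ...) {
  stratum <- match.arg(stratum)
  if (is.null(outcomes)) {
    outcomes <- if (stratum == "all") c("modified_ahei", .stratum_outcomes)
                else .stratum_outcomes
  }
  if (stratum != "all" && "modified_ahei" %in% outcomes) {
    rlang::abort(
      "modified_ahei is a whole-basket composite; not available per stratum",
      class = "nutricart_unsupported_outcome_error")
  }
  if (!"ns_value" %in% names(catalog)) catalog <- label_nutriscore(catalog)
  all_shops <- dplyr::distinct(orders, .data$participant_id, .data$shop_index,
                               .data$condition, .data$post_shop_mood,
                               .data$post_shop_hunger)
  filtered <- orders
  if (stratum != "all") {
    keep_cat <- if (stratum == "foods") "food" else "beverage"
    keep_ids <- catalog$product_id[catalog$category == keep_cat]
    filtered <- dplyr::filter(orders, .data$product_id %in% keep_ids)
  }
  scored <- score_baskets(filtered, catalog, participants)
  # shops emptied by the stratum filter come back with missing outcomes
  scored <- dplyr::left_join(all_shops, scored,
                             by = c("participant_id", "shop_index",
                                    "condition", "post_shop_mood",
                                    "post_shop_hunger"))
  purrr::map_dfr(outcomes, function(oc) {
    diffs <- build_differences(scored, oc, participants)
    fit <- fit_first_difference(diffs, ...)
    dplyr::bind_cols(
      tibble::tibble(stratum = stratum, outcome = oc,
                     n_participants = fit$n_participants,
                     n_observations = fit$n_observations),
      tidy(fit))
  })
}

#' Required sample size for the crossover design
#'
#' Normal-approximation paired-design size for detecting a standardized
#' within-person effect `d` with a two-tailed test at level `alpha`,
#' Bonferroni-adjusted for `n_comparisons` contrasts:
#' `ceiling(((z[1 - alpha/(2k)] + z[power]) / d)^2)`. Under the stated
#' design parameters (d = 0.30, alpha = 0.05, power = 0.90, k = 3) this
#' gives 151 participants.
#'
#' @param effect_size Standardized effect size d (> 0).
#' @param alpha Two-tailed significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param n_comparisons Number of comparisons for the Bonferroni
#'   adjustment (>= 1).
#' @return Integer number of participants.
#' @export
#' @examples
#' sample_size_crossover(0.30, alpha = 0.05, power = 0.90, n_comparisons = 3)
sample_size_crossover <- function(effect_size, alpha = 0.05, power = 0.90,
                                  n_comparisons = 1) {
  if (!(effect_size > 0) || !(alpha > 0 && alpha < 1) ||
      !(power > 0 && power < 1) || n_comparisons < 1) {
    rlang::abort("invalid design parameters", class = "nutricart_domain_error")
  }
  z_a <- stats::qnorm(1 - alpha / (2 * n_comparisons))
  z_b <- stats::qnorm(power)
  as.integer(ceiling(((z_a + z_b) / effect_size)^2))
}

#' Implied reduction in coronary-artery-disease risk
#'
#' Linear extrapolation of an AHEI improvement to a relative risk
#' reduction: a cohort association of `rr_per_10_points` percent lower
#' coronary-artery-disease risk per 10 AHEI points scales the observed
#' basket-level improvement to `(delta_ahei / 10) * rr_per_10_points`,
#' reported to one decimal.
#'
#' @param delta_ahei AHEI-point improvement (>= 0).
#' @param rr_per_10_points Percent risk reduction per 10 AHEI points
#'   (>= 0).
#' @return Percent risk reduction, rounded to one decimal.
#' @export
#' @examples
#' implied_cad_reduction(1.16, 21)
implied_cad_reduction <- function(delta_ahei, rr_per_10_points) {
  stopifnot(delta_ahei >= 0, rr_per_10_points >= 0)
  round(delta_ahei / 10 * rr_per_10_points, 1)
}
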