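# End-to-end pipeline: simulate -> label -> score -> analyze -> report,
# with a run manifest and stage-level logging of record counts.

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Format an effect table in publication layout
#'
#' Renders contrast rows the way crossover trial reports print them: one
#' row per contrast (MTL vs Control; incremental NS over MTL; NS vs
#' Control) with the standard error in parentheses underneath and
#' significance stars (* p < 0.05, ** p < 0.01).
#'
#' @param effects A tidy effect table (from [tidy.fd_fit()] or
#'   [run_crossover()]) with `term`, `estimate`, `std.error`, `p.value`,
#'   and optionally `outcome` columns.
#' @return A character vector of report lines.
#' @export
format_effect_report <- function(effects) {
  labels <- c(alpha = "alpha (MTL vs Control)",
              beta_ns = "beta_NS (incremental effect of NS over MTL)",
              alpha_plus_beta = "alpha + beta_NS (NS vs Control)",
              beta_m = "beta_M (moderator)",
              beta_int = "beta_int (moderator x NS)",
              beta_m_plus_int = "beta_M + beta_int")
  if (!"outcome" %in% names(effects)) effects$outcome <- "outcome"
  lines <- character(0)
  for (oc in unique(effects$outcome)) {
    rows <- effects[effects$outcome == oc, ]
    lines <- c(lines, paste0("Outcome: ", oc))
    for (i in seq_len(nrow(rows))) {
      lines <- c(lines,
                 sprintf("  %-46s %8.3f%s", labels[[rows$term[i]]],
                         rows$estimate[i], significance_stars(rows$p.value[i])),
                 sprintf("  %-46s (%.3f)", "(s.e.)", rows$std.error[i]))
    }
    lines <- c(lines, "")
  }
  c(lines, "* p < 0.05, ** p < 0.01.")
}

descriptives_table <- function(participants) {
  pct <- function(x) 100 * mean(x)
  tibble::tibble(
    variable = c("Age (years)", "Body mass index (kg/m2)", "Female (%)",
                 "University education and above (%)",
                 "Household income >= $10,000/month (%)",
                 "Adults in household (mean)"),
    value = c(mean(participants$age_years), mean(participants$bmi_kg_m2),
              pct(participants$female), pct(participants$high_education),
              pct(participants$high_income),
              mean(participants$n_adults_in_household)),
    sd = c(stats::sd(participants$age_years), stats::sd(participants$bmi_kg_m2),
           NA, NA, NA, stats::sd(participants$n_adults_in_household)))
}

control_characteristics <- function(summaries) {
  control <- dplyr::filter(summaries, .data$condition == "Control")
  num <- dplyr::select(control, "modified_ahei", "avg_nutriscore",
                       dplyr::starts_with("total_"),
                       dplyr::starts_with("mean_"), "kcal_per_dollar")
  tibble::tibble(
    outcome = names(num),
    mean = vapply(num, mean, numeric(1), na.rm = TRUE),
    ci_lo = vapply(num, function(x) {
      m <- mean(x, na.rm = TRUE)
      m - 1.96 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
    }, numeric(1)),
    ci_hi = vapply(num, function(x) {
      m <- mean(x, na.rm = TRUE)
      m + 1.96 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
    }, numeric(1)))
}

#' Run the full pipeline
#'
#' Executes simulate -> label -> score -> analyze -> report under one
#' configuration, writing the three input tables, the per-shop basket
#' summaries, the effect tables and a human-readable report to `outdir`,
#' and returning a manifest that makes every output traceable (config
#' hash, seed, paths, record counts and stage timings). Re-running with
#' the same configuration reproduces the outputs exactly.
#'
#' @param config A [trial_config()] (or path to its YAML form).
#' @param outdir Output directory, created if missing.
#' @param outcomes Outcomes to analyze; default modified AHEI and average
#'   Nutri-Score.
#' @param verbose Emit stage-level progress messages.
#' @return The manifest, a list with `seed`, `config_hash`, `paths`,
#'   `counts`, `timings_s`, `package_version`.
#' @export
run_pipeline <- function(config = trial_config(), outdir = tempfile("nutricart_"),
                         outcomes = c("modified_ahei", "avg_nutriscore"),
                         verbose = TRUE) {
  if (is.character(config)) config <- read_trial_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", stage, "' failed: ",
                          conditionMessage(e)),
                   class = "nutricart_stage_error", parent = e)
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  sim <- tick("simulate", {
    catalog <- generate_catalog(config)
    participants <- generate_participants(config)
    list(catalog = catalog, participants = participants)
  })
  stage_log(verbose, "simulate: %d products, %d participants",
            nrow(sim$catalog), nrow(sim$participants))
  labeled <- tick("label", label_catalog(sim$catalog))
  orders <- tick("shops", simulate_shops(labeled, sim$participants, config))
  stage_log(verbose, "shops: %d order lines, %d shops", nrow(orders),
            dplyr::n_distinct(paste(orders$participant_id, orders$shop_index)))
  tick("validate", validate_orders(orders, labeled, config$min_spend,
                                   config$max_spend))
  summaries <- tick("score", score_baskets(orders, labeled, sim$participants))
  stage_log(verbose, "score: %d basket summaries", nrow(summaries))
  effects <- tick("analyze", purrr::map_dfr(outcomes, function(oc) {
    diffs <- build_differences(summaries, oc, sim$participants)
    fit <- fit_first_difference(diffs)
    dplyr::bind_cols(tibble::tibble(outcome = oc,
                                    n_participants = fit$n_participants,
                                    n_observations = fit$n_observations),
                     tidy(fit))
  }))
  stage_log(verbose, "analyze: %d effect rows over %d outcome(s)",
            nrow(effects), length(outcomes))

  paths <- list(
    catalog = file.path(outdir, "catalog.csv"),
    participants = file.path(outdir, "participants.csv"),
    orders = file.path(outdir, "orders.csv"),
    summaries = file.path(outdir, "basket_summaries.csv"),
    effects = file.path(outdir, "effect_table.csv"),
    report = file.path(outdir, "report.txt"),
    manifest = file.path(outdir, "manifest.yaml"))
  tick("report", {
    readr::write_csv(labeled, paths$catalog)
    readr::write_csv(sim$participants, paths$participants)
    readr::write_csv(orders, paths$orders)
    readr::write_csv(summaries, paths$summaries)
    readr::write_csv(effects, paths$effects)
    desc <- descriptives_table(sim$participants)
    ctrl <- control_characteristics(summaries)
    report <- c(
      "== Cohort descriptive statistics ==",
      sprintf("  %-42s %8.2f %s", desc$variable, desc$value,
              ifelse(is.na(desc$sd), "", sprintf("(%.2f)", desc$sd))),
      "",
      "== Control-condition dietary characteristics ==",
      sprintf("  %-28s %10.2f  (%.2f, %.2f)", ctrl$outcome, ctrl$mean,
              ctrl$ci_lo, ctrl$ci_hi),
      "",
      "== Estimated label effects ==",
      format_effect_report(effects))
    writeLines(report, paths$report)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("nutricart")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    paths = lapply(paths, normalizePath, mustWork = FALSE),
    counts = list(products = nrow(labeled),
                  participants = nrow(sim$participants),
                  order_lines = nrow(orders),
                  baskets = nrow(summaries),
                  effect_rows = nrow(effects)),
    timings_s = as.list(round(unlist(timings), 3)))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(manifest)
}

#' Grade distribution plot for a labeled catalog
#'
#' @param catalog A catalog labeled by [label_nutriscore()].
#' @return A ggplot bar chart of grade shares by category.
#' @export
plot_grade_distribution <- function(catalog) {
  dat <- catalog |>
    dplyr::count(.data$category, .data$ns_grade) |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ns_grade, y = .data$share,
                                    fill = .data$ns_grade)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~category) +
    ggplot2::scale_fill_manual(values = c(A = "#038141", B = "#85BB2F",
                                          C = "#FECB02", D = "#EE8100",
                                          E = "#E63E11")) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Nutri-Score grade", y = "Share of products") +
    ggplot2::theme_minimal()
}
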