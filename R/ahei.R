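# Modified AHEI-2010: nine retained components scored 0-10 (maximum 90).
# Alcohol (not sold) and polyunsaturated fat (not on panels) are dropped.

#' Scale basket totals to per-person-per-day intake
#'
#' A weekly household grocery order is converted to individual daily
#' consumption by dividing every quantity by the number of adult household
#' members and by seven days.
#'
#' @param totals A data frame (or named numeric vector) of nutrient or
#'   component totals for one weekly order.
#' @param n_adults Number of adults in the household (>= 1).
#' @return The totals divided by `n_adults * 7`, same shape as the input.
#' @export
#' @examples
#' per_day_per_person(c(energy_kcal = 2800), n_adults = 2)
per_day_per_person <- function(totals, n_adults) {
  if (any(n_adults < 1)) {
    rlang::abort("n_adults must be >= 1", class = "nutricart_domain_error")
  }
  if (is.data.frame(totals)) {
    totals <- tibble::as_tibble(totals)
    num <- vapply(totals, is.numeric, logical(1))
    totals[num] <- totals[num] / (n_adults * 7)
    totals
  } else {
    totals / (n_adults * 7)
  }
}

linear_score <- function(intake, worst, best) {
  # 0 at worst, 10 at best, linear in between, clamped
  pmin(10, pmax(0, 10 * (intake - worst) / (best - worst)))
}

sodium_decile_score <- function(sodium, cutpoints) {
  # decile rank d in 1..10 -> score 10*(10-d)/9: lowest decile 10, highest 0
  if (length(cutpoints) != 9) {
    rlang::abort("sodium cut-points must be the nine interior deciles",
                 class = "nutricart_domain_error")
  }
  d <- 1L + rowSums(outer(sodium, cutpoints, `>`))
  10 * (10 - d) / 9
}

#' Cohort sodium decile cut-points
#'
#' The sodium component of the modified AHEI is scored by decile rank
#' within the analysis cohort; this computes the nine interior decile
#' cut-points of a vector of per-person-per-day sodium intakes.
#'
#' @param sodium_per_day Numeric vector of person-day sodium intakes (mg).
#' @return Numeric vector of nine cut-points.
#' @export
sodium_decile_cutpoints <- function(sodium_per_day) {
  stats::quantile(sodium_per_day, probs = seq(0.1, 0.9, by = 0.1),
                  na.rm = TRUE, names = FALSE, type = 7)
}

#' Score the nine modified-AHEI components
#'
#' Scores per-person-per-day component intakes 0 (worst) to 10 (best) with
#' linear interpolation between the published anchors; sodium is scored by
#' cohort decile rank (lowest decile 10, highest 0). The trans-fat intake
#' is expressed as percent of energy.
#'
#' @param intake A one-row data frame (or named vector/list) with
#'   per-person-per-day quantities: `vegetables`, `fruit` (servings),
#'   `whole_grains` (g), `ssb_juice`, `nuts_legumes`,
#'   `red_processed_meat` (servings), `trans_fat_pct_energy` (% energy),
#'   `long_chain_n3` (mg), `sodium` (mg).
#' @param sodium_cutpoints Nine cohort decile cut-points for sodium (see
#'   [sodium_decile_cutpoints()]).
#' @param anchors Anchor table, by default [ahei_anchors()].
#' @return A tibble with nine rows: `component`, `intake`, `score`.
#' @export
ahei_component_scores <- function(intake, sodium_cutpoints,
                                  anchors = ahei_anchors()) {
  intake <- as.list(intake)
  needed <- c("vegetables", "fruit", "whole_grains", "ssb_juice",
              "nuts_legumes", "red_processed_meat", "trans_fat_pct_energy",
              "long_chain_n3", "sodium")
  missing <- setdiff(needed, names(intake))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing AHEI component intake(s): ",
                        paste(missing, collapse = ", ")),
                 class = "nutricart_scoring_error")
  }
  vals <- c(
    vegetables = intake$vegetables, fruit = intake$fruit,
    whole_grains = intake$whole_grains, ssb_juice = intake$ssb_juice,
    nuts_legumes = intake$nuts_legumes,
    red_processed_meat = intake$red_processed_meat,
    trans_fat = intake$trans_fat_pct_energy,
    long_chain_n3 = intake$long_chain_n3, sodium = intake$sodium)
  anchors <- anchors[match(names(vals), anchors$component), ]
  score <- linear_score(unname(vals), anchors$worst, anchors$best)
  score[names(vals) == "sodium"] <-
    sodium_decile_score(vals[["sodium"]], sodium_cutpoints)
  tibble::tibble(component = anchors$component,
                 intake = unname(vals), score = score)
}

#' Modified AHEI-2010 score of an intake
#'
#' Sums the nine component scores of [ahei_component_scores()]; range 0
#' (every component at its worst anchor) to 90 (perfect diet quality).
#'
#' @inheritParams ahei_component_scores
#' @return A list with `score` (numeric scalar) and `components` (the
#'   nine-row breakdown tibble).
#' @export
modified_ahei <- function(intake, sodium_cutpoints,
                          anchors = ahei_anchors()) {
  comp <- ahei_component_scores(intake, sodium_cutpoints, anchors)
  list(score = sum(comp$score), components = comp)
}

# Per-person-per-day AHEI component intakes of one weekly order, from the
# catalog's per-serving yields. Returns a one-row tibble; an empty order
# yields all-zero intakes (documented behavior).
ahei_intake_from_lines <- function(lines, catalog, n_adults) {
  joined <- dplyr::inner_join(
    lines, dplyr::select(catalog, "product_id", "servings_per_pack",
                         dplyr::all_of(.catalog_ahei_cols),
                         "energy_kcal_100g", "serving_size_g"),
    by = "product_id")
  servings <- joined$quantity * joined$servings_per_pack
  total <- function(col) sum(servings * joined[[col]])
  energy_kcal <- sum(servings * joined$energy_kcal_100g *
                       joined$serving_size_g / 100)
  transfat_g <- total("ahei_transfat_g")
  # trans-fat expressed as % of energy (9 kcal per g of fat); a zero-energy
  # basket has zero trans-fat energy share by convention
  trans_pct <- if (energy_kcal > 0) 100 * transfat_g * 9 / energy_kcal else 0
  weekly <- tibble::tibble(
    vegetables = total("ahei_veg_serv"),
    fruit = total("ahei_fruit_serv"),
    whole_grains = total("ahei_wholegrain_g"),
    ssb_juice = total("ahei_ssb_serv"),
    nuts_legumes = total("ahei_nutleg_serv"),
    red_processed_meat = total("ahei_meat_serv"),
    long_chain_n3 = total("ahei_n3_mg"),
    sodium = total("ahei_sodium_mg"))
  out <- per_day_per_person(weekly, n_adults)
  out$trans_fat_pct_energy <- trans_pct  # a ratio: scaling cancels
  out
}
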