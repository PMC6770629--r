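# Per-order basket outcomes: modified AHEI, serving-weighted average
# Nutri-Score, nutrient totals and per-serving means, spend, kcal/$.

.total_nutrients <- c(
  energy_kcal = "energy_kcal_100g", sugar_g = "sugar_g_100g",
  fat_g = "fat_g_100g", satfat_g = "satfat_g_100g",
  sodium_mg = "sodium_mg_100g", fiber_g = "fiber_g_100g",
  protein_g = "protein_g_100g"
)

#' Serving-weighted average Nutri-Score of a basket
#'
#' Applies A = 5 down to E = 1 to each product and averages over servings
#' purchased: sum(servings_i * value_i) / sum(servings_i) with
#' servings_i = quantity_i * servings_per_pack_i. The result is invariant
#' to splitting one order line into several lines of the same product and
#' to line ordering.
#'
#' @param lines Order lines (`product_id`, `quantity`) of a single basket.
#' @param graded_catalog Catalog annotated by [label_nutriscore()] (needs
#'   `ns_value` and `servings_per_pack`).
#' @return Numeric scalar in 1-5, or `NA` for an empty basket.
#' @export
average_nutriscore <- function(lines, graded_catalog) {
  if (!"ns_value" %in% names(graded_catalog)) {
    rlang::abort("catalog has no ns_value column; run label_nutriscore() first",
                 class = "nutricart_scoring_error")
  }
  joined <- dplyr::inner_join(
    lines,
    dplyr::select(graded_catalog, "product_id", "servings_per_pack", "ns_value"),
    by = "product_id")
  if (anyNA(joined$ns_value)) {
    rlang::abort("ungraded product in basket", class = "nutricart_scoring_error")
  }
  servings <- joined$quantity * joined$servings_per_pack
  if (nrow(joined) == 0 || sum(servings) == 0) return(NA_real_)
  sum(servings * joined$ns_value) / sum(servings)
}

# totals / per-serving means / spend for one basket's lines
nutrient_summaries_one <- function(lines, catalog) {
  joined <- dplyr::inner_join(
    lines,
    dplyr::select(catalog, "product_id", "price_sgd", "servings_per_pack",
                  "serving_size_g", dplyr::all_of(unname(.total_nutrients))),
    by = "product_id")
  servings <- joined$quantity * joined$servings_per_pack
  n_serv <- sum(servings)
  spend <- sum(joined$quantity * joined$price_sgd)
  out <- tibble::tibble(total_spend_sgd = spend, n_servings = n_serv)
  for (k in seq_along(.total_nutrients)) {
    nm <- names(.total_nutrients)[k]
    per_serving <- joined[[.total_nutrients[k]]] * joined$serving_size_g / 100
    tot <- sum(servings * per_serving)
    out[[paste0("total_", nm)]] <- tot
    out[[paste0("mean_", nm, "_serving")]] <- if (n_serv > 0) tot / n_serv else NA_real_
  }
  out$kcal_per_dollar <- if (spend > 0) out$total_energy_kcal / spend else NA_real_
  out
}

#' Score every basket in an orders table
#'
#' Computes the full per-order outcome battery: modified AHEI-2010 (0-90),
#' serving-weighted average Nutri-Score (1-5), totals and serving-weighted
#' per-serving means of energy, sugar, fat, saturated fat, sodium, fiber
#' and protein, total spend and calories per dollar. One row per
#' participant-shop.
#'
#' Sodium's AHEI component needs a cohort reference distribution; by
#' default the decile cut-points are computed over all person-day sodium
#' values in `orders` (pass `sodium_cutpoints` to fix them externally).
#'
#' @param orders Order-line tibble (see [read_orders()]).
#' @param catalog Catalog tibble; graded on the fly if `ns_value` is
#'   absent.
#' @param participants Participant tibble (for the household adult
#'   divisor).
#' @param sodium_cutpoints Optional nine sodium decile cut-points (mg per
#'   person-day).
#' @param rules Beverage grading rules, used only if the catalog still
#'   needs grading.
#' @return A tibble with one row per (participant, shop): identifiers,
#'   condition, survey values, `modified_ahei`, `avg_nutriscore`, and the
#'   nutrient/spend battery.
#' @export
score_baskets <- function(orders, catalog, participants,
                          sodium_cutpoints = NULL,
                          rules = beverage_rules()) {
  orders <- validate_order_schema(orders)
  participants <- tibble::as_tibble(participants)
  if (!"ns_value" %in% names(catalog)) {
    catalog <- label_nutriscore(catalog, rules)
  }
  shops <- orders |>
    dplyr::distinct(.data$participant_id, .data$shop_index, .data$condition,
                    .data$post_shop_mood, .data$post_shop_hunger) |>
    dplyr::left_join(
      dplyr::select(participants, "participant_id", "n_adults_in_household"),
      by = "participant_id")
  if (anyNA(shops$n_adults_in_household)) {
    rlang::abort("orders reference participants missing from the table",
                 class = "nutricart_reference_error")
  }
  lines_by_shop <- orders |>
    dplyr::group_by(.data$participant_id, .data$shop_index) |>
    dplyr::group_split()
  keys <- orders |>
    dplyr::group_by(.data$participant_id, .data$shop_index) |>
    dplyr::group_keys()

  intakes <- purrr::map2_dfr(lines_by_shop, keys$participant_id, function(ln, pid) {
    n_ad <- shops$n_adults_in_household[match(pid, shops$participant_id)]
    ahei_intake_from_lines(ln, catalog, n_ad)
  })
  if (is.null(sodium_cutpoints)) {
    sodium_cutpoints <- sodium_decile_cutpoints(intakes$sodium)
  }
  scored <- purrr::pmap_dbl(
    list(seq_len(nrow(intakes))),
    function(i) modified_ahei(intakes[i, ], sodium_cutpoints)$score)
  summaries <- purrr::map_dfr(lines_by_shop, nutrient_summaries_one,
                              catalog = catalog)
  avg_ns <- purrr::map_dbl(lines_by_shop, average_nutriscore,
                           graded_catalog = catalog)
  keys |>
    dplyr::left_join(shops, by = c("participant_id", "shop_index")) |>
    dplyr::bind_cols(tibble::tibble(modified_ahei = scored,
                                    avg_nutriscore = avg_ns)) |>
    dplyr::bind_cols(summaries)
}
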