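# Multiple Traffic Light coloring per the UK front-of-pack technical
# guidance: per-100 g bands for fat, saturates, sugars and salt, with
# per-portion red overrides for large portions.

.mtl_nutrients <- c("fat", "saturates", "sugars", "salt")

#' Multiple Traffic Light colors for a nutrient panel
#'
#' Colors fat, saturates, sugars and salt green/amber/red from per-100 g
#' values (salt derived from sodium at 2.5 g per 1000 mg). Boundaries are
#' inclusive on the low side: a value exactly at the green maximum is
#' green, exactly at the amber maximum is amber. A nutrient is forced red
#' when the per-portion quantity exceeds the portion trigger, applied to
#' food portions over 100 g (beverages: bands halved, trigger applied over
#' 150 g). Also reports the per-serving energy and each nutrient's
#' per-serving percentage of the EU reference intake, as displayed on the
#' label.
#'
#' @param panel Data frame with per-100 g columns `fat_g_100g`,
#'   `satfat_g_100g`, `sugar_g_100g`, `sodium_mg_100g`,
#'   `energy_kcal_100g`, and `serving_size_g`.
#' @param category `"food"` or `"beverage"` (scalar, or a `category`
#'   column in `panel`).
#' @return A tibble with columns `fat`, `saturates`, `sugars`, `salt`
#'   (factors green/amber/red), `energy_kcal_serving`, and
#'   `ri_fat`, `ri_saturates`, `ri_sugars`, `ri_salt`, `ri_energy`
#'   (percent of reference intake per serving).
#' @export
#' @examples
#' mtl_colors(data.frame(
#'   fat_g_100g = 2, satfat_g_100g = 0.5, sugar_g_100g = 30,
#'   sodium_mg_100g = 120, energy_kcal_100g = 250, serving_size_g = 30),
#'   category = "food")
mtl_colors <- function(panel, category = NULL) {
  panel <- tibble::as_tibble(panel)
  if (is.null(category)) {
    if (!"category" %in% names(panel)) {
      rlang::abort("supply `category` or a category column",
                   class = "nutricart_scoring_error")
    }
    category <- panel$category
  }
  category <- rep_len(category, nrow(panel))
  require_fields(panel, c("fat_g_100g", "satfat_g_100g", "sugar_g_100g",
                          "sodium_mg_100g", "energy_kcal_100g",
                          "serving_size_g"))
  per100 <- cbind(
    fat = panel$fat_g_100g,
    saturates = panel$satfat_g_100g,
    sugars = panel$sugar_g_100g,
    salt = panel$sodium_mg_100g * .salt_g_per_sodium_mg
  )
  serving <- panel$serving_size_g
  per_serving <- per100 * serving / 100

  food_bands <- mtl_bands("food")
  bev_bands <- mtl_bands("beverage")
  colors <- matrix(NA_character_, nrow(panel), length(.mtl_nutrients),
                   dimnames = list(NULL, .mtl_nutrients))
  for (j in seq_along(.mtl_nutrients)) {
    nut <- .mtl_nutrients[j]
    is_bev <- category == "beverage"
    green_max <- ifelse(is_bev, bev_bands$green_max[j], food_bands$green_max[j])
    amber_max <- ifelse(is_bev, bev_bands$amber_max[j], food_bands$amber_max[j])
    portion_red <- ifelse(is_bev, bev_bands$portion_red[j], food_bands$portion_red[j])
    portion_floor <- ifelse(is_bev, 150, 100)
    col <- ifelse(per100[, nut] <= green_max, "green",
                  ifelse(per100[, nut] <= amber_max, "amber", "red"))
    force_red <- serving > portion_floor & per_serving[, nut] > portion_red
    col[force_red] <- "red"
    colors[, j] <- col
  }
  ri <- reference_intakes()
  out <- tibble::as_tibble(colors)
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ factor(.x, levels = c("green", "amber", "red"))))
  out$energy_kcal_serving <- panel$energy_kcal_100g * serving / 100
  out$ri_fat <- unname(100 * per_serving[, "fat"] / ri[["fat"]])
  out$ri_saturates <- unname(100 * per_serving[, "saturates"] / ri[["saturates"]])
  out$ri_sugars <- unname(100 * per_serving[, "sugars"] / ri[["sugars"]])
  out$ri_salt <- unname(100 * per_serving[, "salt"] / ri[["salt"]])
  out$ri_energy <- 100 * out$energy_kcal_serving / ri[["energy_kcal"]]
  out
}

#' Append MTL colors to a catalog
#'
#' @param catalog Validated catalog tibble.
#' @return The catalog with columns `mtl_fat`, `mtl_saturates`,
#'   `mtl_sugars`, `mtl_salt`, `mtl_energy_kcal_serving`, and `mtl_score`,
#'   a 1-5 healthiness summary used by the shopper simulator (2 points per
#'   green, 1 per amber, 0 per red, rescaled so all-green is 5 and
#'   all-red is 1).
#' @export
label_mtl <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  res <- mtl_colors(catalog)
  color_pts <- vapply(.mtl_nutrients, function(n) {
    3L - as.integer(res[[n]])  # green 2, amber 1, red 0
  }, integer(nrow(catalog)))
  if (nrow(catalog) == 1L) color_pts <- matrix(color_pts, nrow = 1)
  score <- 1 + 4 * rowSums(color_pts) / 8
  dplyr::bind_cols(
    catalog,
    stats::setNames(res[.mtl_nutrients],
                    paste0("mtl_", .mtl_nutrients)),
    tibble::tibble(mtl_energy_kcal_serving = res$energy_kcal_serving,
                   mtl_score = score))
}

#' Annotate a catalog with both label schemes
#'
#' Convenience wrapper running [label_nutriscore()] then [label_mtl()].
#'
#' @inheritParams label_nutriscore
#' @return The catalog with both sets of label columns.
#' @export
label_catalog <- function(catalog, rules = beverage_rules()) {
  label_mtl(label_nutriscore(catalog, rules))
}
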