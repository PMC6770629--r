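# Nutri-Score grading: the original food algorithm, and a transparent
# sugar-first surrogate for beverages (the Singapore HPB beverage scheme the
# trial adapted is proprietary; see beverage_rules()).

points_from_bands <- function(x, bands) {
  # one point per threshold strictly exceeded; vectorized over x
  rowSums(outer(x, bands, `>`))
}

grade_from_points <- function(final_points) {
  breaks <- .ns_grade_breaks
  grade <- dplyr::case_when(
    final_points <= breaks[["A"]] ~ "A",
    final_points <= breaks[["B"]] ~ "B",
    final_points <= breaks[["C"]] ~ "C",
    final_points <= breaks[["D"]] ~ "D",
    TRUE ~ "E"
  )
  factor(grade, levels = c("A", "B", "C", "D", "E"))
}

grade_numeric_value <- function(grade) {
  # A = 5 down to E = 1
  6 - as.integer(factor(grade, levels = c("A", "B", "C", "D", "E")))
}

require_fields <- function(df, fields) {
  for (f in fields) {
    if (!f %in% names(df) || anyNA(df[[f]])) {
      rlang::abort(paste0("scoring requires nutrient field '", f, "'"),
                   class = "nutricart_scoring_error")
    }
  }
}

#' Nutri-Score for foods
#'
#' Applies the original food algorithm: negative points (0-10 each) for
#' energy, sugars, saturated fat and sodium per 100 g; positive points
#' (0-5 each) for fruit/vegetable/nut/legume content, fiber and protein.
#' Protein points are withheld when negative points reach 11 unless the
#' fruit/vegetable component already scores its maximum of 5. Final points
#' (negative minus positive) map to grades A (<= -1), B (0-2), C (3-10),
#' D (11-18), E (>= 19), and to the numeric value A = 5 ... E = 1 used for
#' basket averaging. Band boundaries follow the published "more than"
#' convention: a value exactly on a threshold stays in the lower band.
#'
#' @param panel A data frame with per-100 g columns `energy_kj_100g`,
#'   `sugar_g_100g`, `satfat_g_100g`, `sodium_mg_100g`, `fiber_g_100g`,
#'   `protein_g_100g`, `fvnl_percent` (one row per product; extra columns
#'   are carried through untouched is not needed - only the result tibble
#'   is returned).
#' @return A tibble with one row per input row: `negative_points`,
#'   `positive_points`, `final_points`, `grade`, `numeric_value`.
#' @export
#' @examples
#' nutriscore_food(data.frame(
#'   energy_kj_100g = 1500, sugar_g_100g = 20, satfat_g_100g = 4,
#'   sodium_mg_100g = 300, fiber_g_100g = 2, protein_g_100g = 6,
#'   fvnl_percent = 10))
nutriscore_food <- function(panel) {
  panel <- tibble::as_tibble(panel)
  require_fields(panel, c("energy_kj_100g", "sugar_g_100g", "satfat_g_100g",
                          "sodium_mg_100g", "fiber_g_100g", "protein_g_100g",
                          "fvnl_percent"))
  neg <- points_from_bands(panel$energy_kj_100g, .ns_negative_bands$energy_kj) +
    points_from_bands(panel$sugar_g_100g, .ns_negative_bands$sugar_g) +
    points_from_bands(panel$satfat_g_100g, .ns_negative_bands$satfat_g) +
    points_from_bands(panel$sodium_mg_100g, .ns_negative_bands$sodium_mg)
  fvnl_pts <- points_from_bands(panel$fvnl_percent, .ns_positive_bands$fvnl_percent)
  fiber_pts <- points_from_bands(panel$fiber_g_100g, .ns_positive_bands$fiber_g)
  protein_pts <- points_from_bands(panel$protein_g_100g, .ns_positive_bands$protein_g)
  protein_counted <- ifelse(neg >= 11 & fvnl_pts < 5, 0, protein_pts)
  pos <- fvnl_pts + fiber_pts + protein_counted
  final <- neg - pos
  grade <- grade_from_points(final)
  tibble::tibble(
    negative_points = as.integer(neg),
    positive_points = as.integer(pos),
    final_points = as.integer(final),
    grade = grade,
    numeric_value = grade_numeric_value(grade)
  )
}

#' Beverage grading rules
#'
#' Configuration for the sugar-first beverage surrogate used in place of
#' the proprietary Singapore HPB beverage score. A beverage with zero
#' sugar is always grade A. Otherwise the grade comes from ascending sugar
#' thresholds (g/100 g): at or below `sugar_max[k]` earns the k-th grade
#' of B, C, D; above the last threshold is E. A beverage whose energy
#' density exceeds `energy_bump_kcal` (kcal/100 g) is bumped one grade
#' worse (never past E). Defaults were fixed once so that the package's
#' default synthetic beverage assortment approximates the grade spread the
#' scheme is meant to produce (roughly 29/11/3/3/54% A-E).
#'
#' @param sugar_max Ascending numeric vector of three sugar thresholds for
#'   grades B, C, D.
#' @param energy_bump_kcal Energy density (kcal/100 g) above which the
#'   grade worsens one step.
#' @return A list of class `beverage_rules`.
#' @export
beverage_rules <- function(sugar_max = c(2.5, 4.5, 6.5),
                           energy_bump_kcal = 60) {
  stopifnot(length(sugar_max) == 3, !is.unsorted(sugar_max),
            all(sugar_max > 0), energy_bump_kcal > 0)
  structure(list(sugar_max = sugar_max,
                 energy_bump_kcal = energy_bump_kcal),
            class = "beverage_rules")
}

#' Modified Nutri-Score for beverages
#'
#' Grades beverages with the sugar-first surrogate scheme described in
#' [beverage_rules()]: zero sugar is grade A by definition; other grades
#' follow configurable sugar thresholds with an energy-density bump. Point
#' fields are reported as `NA` because this scheme is not points-based.
#'
#' @param panel Data frame with per-100 g columns `sugar_g_100g` and
#'   `energy_kcal_100g`, and a `category` column which must be
#'   `"beverage"` throughout.
#' @param rules A [beverage_rules()] object.
#' @return A tibble matching [nutriscore_food()]'s columns.
#' @export
nutriscore_beverage <- function(panel, rules = beverage_rules()) {
  panel <- tibble::as_tibble(panel)
  if ("category" %in% names(panel) && any(panel$category != "beverage")) {
    rlang::abort("nutriscore_beverage() received non-beverage rows",
                 class = "nutricart_category_error")
  }
  require_fields(panel, c("sugar_g_100g", "energy_kcal_100g"))
  sugar <- panel$sugar_g_100g
  idx <- 1L + points_from_bands(sugar, rules$sugar_max)  # 1..4 -> B..E
  idx <- ifelse(panel$energy_kcal_100g > rules$energy_bump_kcal,
                pmin(idx + 1L, 4L), idx)
  grade <- c("B", "C", "D", "E")[idx]
  grade[sugar == 0] <- "A"
  grade <- factor(grade, levels = c("A", "B", "C", "D", "E"))
  tibble::tibble(
    negative_points = NA_integer_,
    positive_points = NA_integer_,
    final_points = NA_integer_,
    grade = grade,
    numeric_value = grade_numeric_value(grade)
  )
}

#' Grade every product in a catalog
#'
#' Dispatches foods to [nutriscore_food()] and beverages to
#' [nutriscore_beverage()], and appends the grade columns to the catalog.
#'
#' @param catalog Validated catalog tibble.
#' @param rules Beverage grading rules.
#' @return The catalog with added columns `ns_negative_points`,
#'   `ns_positive_points`, `ns_final_points`, `ns_grade`, `ns_value`.
#' @export
label_nutriscore <- function(catalog, rules = beverage_rules()) {
  catalog <- tibble::as_tibble(catalog)
  res <- tibble::tibble(
    negative_points = rep(NA_integer_, nrow(catalog)),
    positive_points = NA_integer_, final_points = NA_integer_,
    grade = factor(rep(NA, nrow(catalog)), levels = c("A", "B", "C", "D", "E")),
    numeric_value = NA_integer_)
  is_food <- catalog$category == "food"
  if (any(is_food)) res[is_food, ] <- nutriscore_food(catalog[is_food, ])
  if (any(!is_food)) res[!is_food, ] <- nutriscore_beverage(catalog[!is_food, ], rules)
  dplyr::bind_cols(catalog, stats::setNames(
    res, c("ns_negative_points", "ns_positive_points", "ns_final_points",
           "ns_grade", "ns_value")))
}
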