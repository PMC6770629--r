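# Catalog / participants / orders data model and I/O.
#
# All three tables are plain CSV with documented headers; readers validate
# invariants up front so downstream scoring can assume clean inputs.

.catalog_nutrients <- c(
  "energy_kj_100g", "energy_kcal_100g", "sugar_g_100g", "fat_g_100g",
  "satfat_g_100g", "sodium_mg_100g", "fiber_g_100g", "protein_g_100g",
  "transfat_g_100g", "fvnl_percent"
)

.catalog_ahei_cols <- c(
  "ahei_veg_serv", "ahei_fruit_serv", "ahei_wholegrain_g", "ahei_ssb_serv",
  "ahei_nutleg_serv", "ahei_meat_serv", "ahei_transfat_g", "ahei_n3_mg",
  "ahei_sodium_mg"
)

.catalog_cols <- c(
  "product_id", "name", "category", "price_sgd", "servings_per_pack",
  "serving_size_g", .catalog_nutrients, .catalog_ahei_cols
)

.participant_cols <- c(
  "participant_id", "n_adults_in_household", "age_years", "bmi_kg_m2",
  "female", "high_education", "high_income", "seq_shop1", "seq_shop2",
  "seq_shop3"
)

.order_cols <- c(
  "participant_id", "shop_index", "condition", "product_id", "quantity",
  "post_shop_mood", "post_shop_hunger"
)

.conditions <- c("Control", "MTL", "NS")

abort_schema <- function(missing, what) {
  rlang::abort(
    paste0(what, " is missing required column(s): ",
           paste(missing, collapse = ", ")),
    class = "nutricart_schema_error"
  )
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "nutricart_validation_error")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) abort_schema(missing, what)
  invisible(df)
}

#' Validate a product catalog
#'
#' Checks the schema and physical invariants of a catalog table: nutrient
#' quantities and AHEI yields non-negative, saturated fat not exceeding
#' total fat, fruit/vegetable/nut/legume percentage at most 100, positive
#' prices and serving counts, category one of `food`/`beverage`, and kJ/kcal
#' energy consistency within 2% when both are supplied. When only one
#' energy unit is present the other is derived at 4.184 kJ/kcal.
#'
#' @param catalog A data frame with one row per product (see
#'   [read_catalog()] for the column set).
#' @return The validated catalog as a tibble, with both energy columns
#'   filled in.
#' @export
validate_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  core <- setdiff(.catalog_cols, c("energy_kj_100g", "energy_kcal_100g"))
  check_columns(catalog, core, "catalog")
  has_kj <- "energy_kj_100g" %in% names(catalog)
  has_kcal <- "energy_kcal_100g" %in% names(catalog)
  if (!has_kj && !has_kcal) abort_schema("energy_kj_100g", "catalog")
  if (!has_kj) catalog$energy_kj_100g <- catalog$energy_kcal_100g * .kj_per_kcal
  if (!has_kcal) catalog$energy_kcal_100g <- catalog$energy_kj_100g / .kj_per_kcal
  kj <- catalog$energy_kj_100g
  kcal <- catalog$energy_kcal_100g
  fillable <- is.na(kj) & !is.na(kcal)
  catalog$energy_kj_100g[fillable] <- kcal[fillable] * .kj_per_kcal
  fillable <- is.na(kcal) & !is.na(kj)
  catalog$energy_kcal_100g[fillable] <- kj[fillable] / .kj_per_kcal

  bad_cat <- !catalog$category %in% c("food", "beverage")
  if (any(bad_cat)) {
    abort_validation(paste0(
      "catalog: invalid category for product(s) ",
      paste(catalog$product_id[bad_cat], collapse = ", ")))
  }
  if (anyDuplicated(catalog$product_id)) {
    abort_validation("catalog: duplicated product_id")
  }
  for (col in c(.catalog_nutrients, .catalog_ahei_cols)) {
    bad <- !is.na(catalog[[col]]) & catalog[[col]] < 0
    if (any(bad)) {
      abort_validation(paste0(
        "catalog: negative ", col, " for product(s) ",
        paste(catalog$product_id[bad], collapse = ", ")))
    }
  }
  bad <- catalog$satfat_g_100g > catalog$fat_g_100g + 1e-9
  if (any(bad, na.rm = TRUE)) {
    abort_validation(paste0(
      "catalog: saturated fat exceeds total fat for product(s) ",
      paste(catalog$product_id[which(bad)], collapse = ", ")))
  }
  bad <- catalog$fvnl_percent > 100
  if (any(bad, na.rm = TRUE)) {
    abort_validation(paste0(
      "catalog: fvnl_percent above 100 for product(s) ",
      paste(catalog$product_id[which(bad)], collapse = ", ")))
  }
  if (any(catalog$price_sgd <= 0, na.rm = TRUE)) {
    abort_validation(paste0(
      "catalog: non-positive price for product(s) ",
      paste(catalog$product_id[which(catalog$price_sgd <= 0)], collapse = ", ")))
  }
  if (any(catalog$servings_per_pack <= 0, na.rm = TRUE)) {
    abort_validation("catalog: servings_per_pack must be positive")
  }
  both <- !is.na(kj) & !is.na(kcal) & kcal > 0
  ratio <- kj[both] / (kcal[both] * .kj_per_kcal)
  bad <- abs(ratio - 1) > 0.02
  if (any(bad)) {
    abort_validation(paste0(
      "catalog: kJ/kcal energy mismatch beyond 2% for product(s) ",
      paste(catalog$product_id[both][bad], collapse = ", ")))
  }
  catalog
}

#' Read a product catalog from CSV
#'
#' The file must carry one row per product with columns: `product_id`,
#' `name`, `category` (`food`/`beverage`), `price_sgd`,
#' `servings_per_pack`, `serving_size_g`, the per-100 g nutrient panel
#' (`energy_kj_100g`, `energy_kcal_100g`, `sugar_g_100g`, `fat_g_100g`,
#' `satfat_g_100g`, `sodium_mg_100g`, `fiber_g_100g`, `protein_g_100g`,
#' `transfat_g_100g`, `fvnl_percent`), and per-serving AHEI component
#' yields (`ahei_veg_serv`, `ahei_fruit_serv`, `ahei_wholegrain_g`,
#' `ahei_ssb_serv`, `ahei_nutleg_serv`, `ahei_meat_serv`,
#' `ahei_transfat_g`, `ahei_n3_mg`, `ahei_sodium_mg`). AHEI yields are
#' explicit catalog annotations because mapping products to diet-quality
#' food groups is not derivable from a nutrition panel.
#'
#' @param path Path to a CSV file.
#' @return A validated catalog tibble.
#' @seealso [validate_catalog()], [write_catalog()]
#' @export
read_catalog <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_catalog(df)
}

#' Write a catalog to CSV
#' @param catalog A catalog tibble.
#' @param path Output file path.
#' @return `catalog`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_csv(catalog, path)
  invisible(catalog)
}

#' Read and validate a participant table
#'
#' Columns: `participant_id`, `n_adults_in_household` (>= 1), `age_years`,
#' `bmi_kg_m2`, `female`, `high_education`, `high_income` (0/1 indicators),
#' and the randomized condition sequence `seq_shop1`..`seq_shop3`, which
#' must be a permutation of Control/MTL/NS.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_participants <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_participants(df)
}

#' @rdname read_participants
#' @param participants A participant data frame to validate in memory.
#' @export
validate_participants <- function(participants) {
  participants <- tibble::as_tibble(participants)
  check_columns(participants, .participant_cols, "participants")
  if (any(participants$n_adults_in_household < 1)) {
    abort_validation("participants: n_adults_in_household must be >= 1")
  }
  seqs <- participants[, c("seq_shop1", "seq_shop2", "seq_shop3")]
  ok <- apply(seqs, 1, function(s) setequal(s, .conditions))
  if (!all(ok)) {
    abort_validation(paste0(
      "participants: sequence is not a permutation of Control/MTL/NS for ",
      paste(participants$participant_id[!ok], collapse = ", ")))
  }
  participants
}

#' Read an orders table
#'
#' One row per order line: `participant_id`, `shop_index` (1-3),
#' `condition`, `product_id`, `quantity` (packs), and the post-shop survey
#' values `post_shop_mood`, `post_shop_hunger` (ordinal, repeated across
#' the lines of a shop and checked for consistency).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of order lines.
#' @export
read_orders <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_order_schema(df)
}

validate_order_schema <- function(orders) {
  orders <- tibble::as_tibble(orders)
  check_columns(orders, .order_cols, "orders")
  bad <- !orders$condition %in% .conditions
  if (any(bad)) abort_validation("orders: condition must be Control/MTL/NS")
  if (any(orders$quantity <= 0)) {
    abort_validation("orders: quantities must be positive")
  }
  per_shop <- dplyr::summarise(
    dplyr::group_by(orders, .data$participant_id, .data$shop_index),
    n_cond = dplyr::n_distinct(.data$condition),
    n_mood = dplyr::n_distinct(.data$post_shop_mood),
    n_hunger = dplyr::n_distinct(.data$post_shop_hunger),
    .groups = "drop")
  if (any(per_shop$n_cond > 1 | per_shop$n_mood > 1 | per_shop$n_hunger > 1)) {
    abort_validation(
      "orders: condition and survey values must be constant within a shop")
  }
  orders
}

#' Validate order spend windows
#'
#' Checks that every product id resolves in the catalog and that each
#' shop's total spend lies inside the allowed window (boundaries
#' inclusive). The verdict is invariant to the ordering of lines and the
#' function is idempotent.
#'
#' @param orders Order-line tibble (see [read_orders()]); may contain one
#'   or many shops.
#' @param catalog Validated catalog tibble.
#' @param min_spend,max_spend Spend window in SGD (defaults \$50-\$100).
#' @return `orders` (as a tibble), invisibly unchanged, if all shops pass.
#'   Unknown products raise a reference error; an out-of-window shop
#'   raises a spend-window error carrying the computed total.
#' @export
validate_orders <- function(orders, catalog, min_spend = 50, max_spend = 100) {
  orders <- validate_order_schema(orders)
  unknown <- setdiff(orders$product_id, catalog$product_id)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("orders reference unknown product_id(s): ",
             paste(utils::head(unknown, 5), collapse = ", ")),
      class = "nutricart_reference_error")
  }
  totals <- orders |>
    dplyr::left_join(
      dplyr::select(catalog, "product_id", "price_sgd"), by = "product_id") |>
    dplyr::group_by(.data$participant_id, .data$shop_index) |>
    dplyr::summarise(
      total = sum(.data$quantity * .data$price_sgd), .groups = "drop")
  # compare at cent precision: prices are two-decimal currency
  cents <- round(totals$total * 100)
  bad <- cents < round(min_spend * 100) | cents > round(max_spend * 100)
  if (any(bad)) {
    first <- totals[which(bad)[1], ]
    rlang::abort(
      sprintf(
        "order %s/shop %d total $%.2f outside spend window [$%.2f, $%.2f] (%d shop(s) affected)",
        first$participant_id, first$shop_index, first$total,
        min_spend, max_spend, sum(bad)),
      class = "nutricart_spend_window_error",
      total = totals$total[bad])
  }
  invisible(orders)
}

#' @rdname validate_orders
#' @export
validate_order <- validate_orders
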