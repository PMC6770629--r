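# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# one catalog row with sane defaults, overridable per field
catalog_row <- function(product_id, ...) {
  row <- tibble::tibble(
    product_id = product_id, name = product_id, category = "food",
    price_sgd = 5, servings_per_pack = 2, serving_size_g = 100,
    energy_kcal_100g = 100, energy_kj_100g = 100 * 4.184,
    sugar_g_100g = 5, fat_g_100g = 3, satfat_g_100g = 1,
    sodium_mg_100g = 100, fiber_g_100g = 1, protein_g_100g = 4,
    transfat_g_100g = 0, fvnl_percent = 0,
    ahei_veg_serv = 0, ahei_fruit_serv = 0, ahei_wholegrain_g = 0,
    ahei_ssb_serv = 0, ahei_nutleg_serv = 0, ahei_meat_serv = 0,
    ahei_transfat_g = 0, ahei_n3_mg = 0, ahei_sodium_mg = 100)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  if (!"energy_kj_100g" %in% names(over) && "energy_kcal_100g" %in% names(over)) {
    row$energy_kj_100g <- row$energy_kcal_100g * 4.184
  }
  row
}

toy_catalog <- function() {
  dplyr::bind_rows(
    # grade A food: all-negative zeros won't happen, keep a green vegetable
    catalog_row("VEG", energy_kcal_100g = 35, sugar_g_100g = 2,
                fat_g_100g = 0.3, satfat_g_100g = 0.1, sodium_mg_100g = 30,
                fiber_g_100g = 3, protein_g_100g = 2, fvnl_percent = 100,
                ahei_veg_serv = 1, ahei_sodium_mg = 30, price_sgd = 4),
    # grade E food: saturated candy bar
    catalog_row("CHOC", energy_kcal_100g = 540, sugar_g_100g = 52,
                fat_g_100g = 30, satfat_g_100g = 18, sodium_mg_100g = 150,
                fiber_g_100g = 1, protein_g_100g = 5, price_sgd = 3,
                serving_size_g = 40),
    # zero-sugar beverage: grade A by rule
    catalog_row("WATER", category = "beverage", energy_kcal_100g = 0,
                sugar_g_100g = 0, fat_g_100g = 0, satfat_g_100g = 0,
                sodium_mg_100g = 5, fiber_g_100g = 0, protein_g_100g = 0,
                serving_size_g = 250, price_sgd = 1.5, ahei_sodium_mg = 12.5),
    # sugary drink: grade E, SSB yield
    catalog_row("SODA", category = "beverage", energy_kcal_100g = 44,
                sugar_g_100g = 11, fat_g_100g = 0, satfat_g_100g = 0,
                sodium_mg_100g = 10, fiber_g_100g = 0, protein_g_100g = 0,
                serving_size_g = 250, price_sgd = 2, ahei_ssb_serv = 1,
                ahei_sodium_mg = 25))
}

# order lines for one shop
shop_lines <- function(participant_id, shop_index, condition, product_ids,
                       quantities, mood = 4, hunger = 3) {
  tibble::tibble(
    participant_id = participant_id, shop_index = shop_index,
    condition = condition, product_id = product_ids,
    quantity = quantities, post_shop_mood = mood, post_shop_hunger = hunger)
}

toy_participants <- function(ids = "P1", n_adults = 1) {
  tibble::tibble(
    participant_id = ids, n_adults_in_household = n_adults,
    age_years = 35, bmi_kg_m2 = 23, female = 1, high_education = 1,
    high_income = 0, seq_shop1 = "Control", seq_shop2 = "MTL",
    seq_shop3 = "NS")
}

# independent band-scan Nutri-Score oracle: literal threshold walk,
# structurally unlike the vectorized implementation
oracle_nutriscore_food <- function(energy_kj, sugar, satfat, sodium,
                                   fiber, protein, fvnl) {
  bands <- ns_point_bands()
  scan <- function(v, thresholds) {
    pts <- 0L
    for (th in thresholds) if (v > th) pts <- pts + 1L else break
    pts
  }
  n_e <- scan(energy_kj, bands$negative$energy_kj)
  n_su <- scan(sugar, bands$negative$sugar_g)
  n_sa <- scan(satfat, bands$negative$satfat_g)
  n_so <- scan(sodium, bands$negative$sodium_mg)
  neg <- n_e + n_su + n_sa + n_so
  p_f <- scan(fvnl, bands$positive$fvnl_percent)
  p_fi <- scan(fiber, bands$positive$fiber_g)
  p_pr <- scan(protein, bands$positive$protein_g)
  if (neg >= 11 && p_f < 5) p_pr <- 0L
  final <- neg - (p_f + p_fi + p_pr)
  grade <- if (final <= -1) "A" else if (final <= 2) "B" else
    if (final <= 10) "C" else if (final <= 18) "D" else "E"
  list(negative = neg, positive = p_f + p_fi + p_pr, final = final,
       grade = grade)
}

random_panels <- function(n, seed = 99) {
  set.seed(seed)
  # mix continuous draws with exact band-boundary values to exercise ties
  pick <- function(cont, boundaries) {
    at_boundary <- runif(n) < 0.15
    ifelse(at_boundary, sample(boundaries, n, replace = TRUE), cont)
  }
  b <- ns_point_bands()
  tibble::tibble(
    energy_kj_100g = pick(runif(n, 0, 4000), b$negative$energy_kj),
    sugar_g_100g = pick(runif(n, 0, 60), b$negative$sugar_g),
    satfat_g_100g = pick(runif(n, 0, 15), b$negative$satfat_g),
    sodium_mg_100g = pick(runif(n, 0, 1200), b$negative$sodium_mg),
    fiber_g_100g = pick(runif(n, 0, 8), b$positive$fiber_g),
    protein_g_100g = pick(runif(n, 0, 15), b$positive$protein_g),
    fvnl_percent = pick(runif(n, 0, 100), b$positive$fvnl_percent))
}
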