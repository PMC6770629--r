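small_cfg <- function(seed = 1, ...) {
  trial_config(seed = seed, n_products = 300, n_participants = 24, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  c1 <- generate_catalog(small_cfg(seed = 11))
  c2 <- generate_catalog(small_cfg(seed = 11))
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_catalog(small_cfg(seed = 12))))
  sim1 <- simulate_trial(small_cfg(seed = 11))
  sim2 <- simulate_trial(small_cfg(seed = 11))
  expect_identical(sim1$orders, sim2$orders)
})

test_that("generated panels are internally consistent", {
  catalog <- generate_catalog(small_cfg(seed = 2))
  expect_true(all(catalog$satfat_g_100g <= catalog$fat_g_100g + 1e-9))
  expect_true(all(catalog$fvnl_percent <= 100))
  expect_equal(catalog$energy_kj_100g, catalog$energy_kcal_100g * 4.184)
  expect_true(all(catalog$price_sgd > 0))
  # validate_catalog accepts its own output
  expect_silent(validate_catalog(catalog))
})

test_that("the default catalog approximates the trial's grade spread", {
  lab <- label_nutriscore(generate_catalog(trial_config(seed = 5)))
  food <- prop.table(table(lab$ns_grade[lab$category == "food"]))
  expect_lt(abs(food[["A"]] - 0.26), 0.03)
  expect_lt(abs(food[["C"]] - 0.26), 0.04)
  expect_lt(abs(food[["E"]] - 0.098), 0.03)
  bev <- prop.table(table(lab$ns_grade[lab$category == "beverage"]))
  expect_lt(abs(bev[["A"]] - 0.29), 0.05)
  expect_lt(abs(bev[["E"]] - 0.54), 0.05)
})

test_that("permuted blocks allocate the six sequences equally", {
  p6 <- tibble::tibble(participant_id = sprintf("P%d", 1:6))
  s6 <- assign_sequences(p6, seed = 3)
  seqs <- paste(s6$seq_shop1, s6$seq_shop2, s6$seq_shop3)
  expect_equal(length(unique(seqs)), 6)
  p12 <- tibble::tibble(participant_id = sprintf("P%d", 1:12))
  s12 <- assign_sequences(p12, seed = 3)
  tab <- table(paste(s12$seq_shop1, s12$seq_shop2, s12$seq_shop3))
  expect_true(all(tab == 2))
  expect_identical(assign_sequences(p12, seed = 3), s12)
  # every row is a permutation of the three conditions
  expect_silent(validate_participants(
    dplyr::mutate(s12, n_adults_in_household = 1, age_years = 30,
                  bmi_kg_m2 = 22, female = 1, high_education = 1,
                  high_income = 0)))
})

test_that("every simulated order respects the spend window", {
  sim <- simulate_trial(small_cfg(seed = 21))
  expect_silent(validate_orders(sim$orders, sim$catalog, 50, 100))
  # conditions in orders match the participant's sequence at that shop
  seq_long <- tidyr::pivot_longer(
    sim$participants, dplyr::starts_with("seq_shop"),
    names_to = "shop", values_to = "expected") |>
    dplyr::mutate(shop_index = as.integer(sub("seq_shop", "", shop)))
  check <- dplyr::distinct(sim$orders, participant_id, shop_index, condition) |>
    dplyr::left_join(seq_long, by = c("participant_id", "shop_index"))
  expect_true(all(check$condition == check$expected))
})

test_that("the completion pattern matches the recruited cohort's dropout", {
  cfg <- trial_config(seed = 6, n_products = 300)
  catalog <- label_catalog(generate_catalog(cfg))
  participants <- generate_participants(cfg)
  orders <- simulate_shops(catalog, participants, cfg)
  shops_per <- orders |>
    dplyr::distinct(participant_id, shop_index) |>
    dplyr::count(participant_id)
  n_by_count <- table(factor(shops_per$n, levels = 1:3))
  n0 <- nrow(participants) - nrow(shops_per)
  # expected 14/7/2/145 of 168; allow 4 binomial SDs
  expect_lt(abs(n0 - 14), 4 * sqrt(168 * (14 / 168) * (1 - 14 / 168)))
  expect_lt(abs(n_by_count[["1"]] - 7), 4 * sqrt(168 * (7 / 168)))
  expect_lt(abs(n_by_count[["3"]] - 145), 4 * sqrt(168 * (145 / 168) * (23 / 168)))
  expect_true(all(orders$post_shop_mood %in% 1:7))
})

test_that("a positive NS utility effect raises average Nutri-Score under NS", {
  cfg <- trial_config(seed = 13, n_products = 600, n_participants = 80,
                      gamma_mtl = 0, gamma_ns = 0.4)
  sim <- simulate_trial(cfg)
  s <- score_baskets(sim$orders, sim$catalog, sim$participants)
  est <- tidy(fit_first_difference(build_differences(s, "avg_nutriscore")))
  expect_gt(est$estimate[est$term == "alpha_plus_beta"], 0)
  expect_gt(est$statistic[est$term == "alpha_plus_beta"], 2)
})

test_that("with label effects off, basket quality is equal across conditions", {
  cfg <- trial_config(seed = 17, n_products = 600, n_participants = 80,
                      gamma_mtl = 0, gamma_ns = 0)
  sim <- simulate_trial(cfg)
  s <- score_baskets(sim$orders, sim$catalog, sim$participants)
  est <- tidy(fit_first_difference(build_differences(s, "modified_ahei")))
  expect_lt(abs(est$statistic[est$term == "alpha"]), 4)
  expect_lt(abs(est$statistic[est$term == "alpha_plus_beta"]), 4)
})

test_that("trial configuration round-trips through YAML", {
  cfg <- trial_config(seed = 9, gamma_ns = 0.5, n_products = 123)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  back <- read_trial_config(path)
  expect_equal(back$gamma_ns, 0.5)
  expect_equal(back$n_products, 123)
  expect_equal(back$completion_probs, cfg$completion_probs)
  expect_error(trial_config(seed = NA), class = "nutricart_domain_error")
})
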