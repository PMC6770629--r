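test_that("serving-weighted average Nutri-Score matches hand computations", {
  catalog <- label_nutriscore(toy_catalog())
  # all grade-A basket (VEG and WATER are A)
  all_a <- shop_lines("P1", 1, "Control", c("VEG", "WATER"), c(3, 2))
  expect_equal(average_nutriscore(all_a, catalog), 5)
  # one A and one E product with equal servings -> midpoint 3
  # VEG: 1 pack x 2 servings; CHOC: 1 pack x 2 servings
  mixed <- shop_lines("P1", 1, "Control", c("VEG", "CHOC"), c(1, 1))
  expect_equal(average_nutriscore(mixed, catalog), 3)
})

test_that("average is weighted by servings: 2 A + 1 C gives 13/3", {
  catalog <- dplyr::bind_rows(
    catalog_row("A2", energy_kcal_100g = 30, sugar_g_100g = 1,
                fat_g_100g = 0.2, satfat_g_100g = 0.1, sodium_mg_100g = 10,
                fiber_g_100g = 3, protein_g_100g = 2, fvnl_percent = 100,
                servings_per_pack = 2),
    # final points 3-10 -> C: energy 1200 kJ (3) + sugar 2 (0), no positives
    catalog_row("C1", energy_kcal_100g = 1200 / 4.184, sugar_g_100g = 2,
                fat_g_100g = 1, satfat_g_100g = 0.3, sodium_mg_100g = 10,
                fiber_g_100g = 0, protein_g_100g = 0, fvnl_percent = 0,
                servings_per_pack = 1))
  catalog <- label_nutriscore(catalog)
  expect_equal(as.character(catalog$ns_grade), c("A", "C"))
  lines <- shop_lines("P1", 1, "Control", c("A2", "C1"), c(1, 1))
  expect_equal(average_nutriscore(lines, catalog), 13 / 3)
})

test_that("average is invariant to splitting a line and to line order", {
  catalog <- label_nutriscore(toy_catalog())
  whole <- shop_lines("P1", 1, "Control", c("VEG", "CHOC"), c(4, 1))
  split <- shop_lines("P1", 1, "Control", c("CHOC", "VEG", "VEG"),
                      c(1, 1, 3))
  expect_equal(average_nutriscore(whole, catalog),
               average_nutriscore(split, catalog))
  # empty basket has no defined average
  empty <- shop_lines("P1", 1, "Control", character(0), numeric(0))
  expect_true(is.na(average_nutriscore(empty, catalog)))
})

test_that("nutrient summaries match simple arithmetic", {
  # 1 pack, 2 servings of 100 kcal each, $4 -> 200 kcal, 100/serving, 50/$
  catalog <- catalog_row("X", price_sgd = 4, servings_per_pack = 2,
                         serving_size_g = 100, energy_kcal_100g = 100)
  out <- nutricart:::nutrient_summaries_one(
    shop_lines("P1", 1, "Control", "X", 1), catalog)
  expect_equal(out$total_energy_kcal, 200)
  expect_equal(out$mean_energy_kcal_serving, 100)
  expect_equal(out$kcal_per_dollar, 50)
  expect_equal(out$total_spend_sgd, 4)
  expect_equal(out$n_servings, 2)
})

test_that("summaries agree with a brute-force per-line accumulation", {
  set.seed(42)
  catalog <- generate_catalog(trial_config(seed = 8, n_products = 60))
  lines <- tibble::tibble(
    participant_id = "P1", shop_index = 1L, condition = "Control",
    product_id = sample(catalog$product_id, 20),
    quantity = sample(1:4, 20, replace = TRUE),
    post_shop_mood = 4, post_shop_hunger = 4)
  got <- nutricart:::nutrient_summaries_one(lines, catalog)
  # independent accumulation: explicit loop over lines
  total_kcal <- 0; total_serv <- 0; spend <- 0
  for (i in seq_len(nrow(lines))) {
    p <- catalog[catalog$product_id == lines$product_id[i], ]
    serv <- lines$quantity[i] * p$servings_per_pack
    total_serv <- total_serv + serv
    total_kcal <- total_kcal + serv * p$energy_kcal_100g * p$serving_size_g / 100
    spend <- spend + lines$quantity[i] * p$price_sgd
  }
  expect_equal(got$total_energy_kcal, total_kcal)
  expect_equal(got$mean_energy_kcal_serving, total_kcal / total_serv)
  expect_equal(got$total_spend_sgd, spend)
  expect_equal(got$kcal_per_dollar, total_kcal / spend)
})

test_that("score_baskets returns one row per shop and ignores line order", {
  catalog <- toy_catalog()
  participants <- toy_participants(c("P1", "P2"), n_adults = c(1, 2))
  orders <- dplyr::bind_rows(
    shop_lines("P1", 1, "Control", c("VEG", "CHOC", "SODA"), c(5, 3, 2)),
    shop_lines("P1", 2, "MTL", c("VEG", "WATER"), c(6, 4)),
    shop_lines("P2", 1, "Control", c("CHOC", "SODA"), c(8, 5)))
  out <- score_baskets(orders, catalog, participants)
  expect_equal(nrow(out), 3)
  expect_true(all(out$modified_ahei >= 0 & out$modified_ahei <= 90))
  expect_true(all(out$avg_nutriscore >= 1 & out$avg_nutriscore <= 5))
  expect_equal(out$kcal_per_dollar, out$total_energy_kcal / out$total_spend_sgd)
  shuffled <- orders[sample.int(nrow(orders)), ]
  out2 <- score_baskets(shuffled, catalog, participants)
  expect_equal(dplyr::arrange(out2, participant_id, shop_index),
               dplyr::arrange(out, participant_id, shop_index))
})

test_that("household scaling: doubling quantities and adults leaves AHEI unchanged", {
  catalog <- toy_catalog()
  orders1 <- shop_lines("P1", 1, "Control", c("VEG", "CHOC"), c(4, 2))
  orders2 <- shop_lines("P2", 1, "Control", c("VEG", "CHOC"), c(8, 4))
  participants <- toy_participants(c("P1", "P2"), n_adults = c(1, 2))
  out <- score_baskets(dplyr::bind_rows(orders1, orders2), catalog,
                       participants, sodium_cutpoints = seq(10, 90, 10))
  expect_equal(out$modified_ahei[1], out$modified_ahei[2])
})
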