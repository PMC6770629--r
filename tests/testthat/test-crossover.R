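# summaries builder: one row per shop with a single outcome column y
mk_summaries <- function(participant_id, condition, y,
                         mood = 4, hunger = 4) {
  tibble::tibble(participant_id = participant_id,
                 shop_index = ave(seq_along(condition), participant_id,
                                  FUN = seq_along),
                 condition = condition, y = y,
                 post_shop_mood = mood, post_shop_hunger = hunger)
}

test_that("differences subtract the control shop per participant", {
  s <- mk_summaries("P1", c("Control", "MTL", "NS"), c(40, 42, 41))
  d <- build_differences(s, "y")
  expect_equal(nrow(d), 2)
  expect_equal(d$delta[d$ns_dummy == 0], 2)
  expect_equal(d$delta[d$ns_dummy == 1], 1)
  # participant with no control shop contributes nothing
  s2 <- mk_summaries("P2", c("MTL", "NS"), c(10, 11))
  expect_equal(nrow(build_differences(s2, "y")), 0)
  # duplicate condition is a data error
  s3 <- mk_summaries("P3", c("Control", "MTL", "MTL"), c(1, 2, 3))
  expect_error(build_differences(s3, "y"), class = "nutricart_data_error")
})

test_that("the trial completion pattern yields n = 147 and N = 292", {
  set.seed(2)
  full <- purrr::map_dfr(1:145, function(i) {
    mk_summaries(sprintf("F%03d", i), c("Control", "MTL", "NS"), rnorm(3))
  })
  two_shop <- dplyr::bind_rows(
    mk_summaries("T1", c("Control", "MTL"), rnorm(2)),
    mk_summaries("T2", c("Control", "NS"), rnorm(2)))
  # one-shop participants cannot be differenced
  one_shop <- mk_summaries("O1", "MTL", rnorm(1))
  d <- build_differences(dplyr::bind_rows(full, two_shop, one_shop), "y")
  expect_equal(nrow(d), 292)
  expect_equal(dplyr::n_distinct(d$participant_id), 147)
})

test_that("OLS on the dummy reproduces group-mean contrasts", {
  set.seed(31)
  for (rep in 1:20) {
    d <- simulate_differences(40, effect_mtl = rnorm(1), effect_ns = rnorm(1),
                              seed = rep)
    fit <- fit_first_difference(d)
    est <- tidy(fit)
    m0 <- mean(d$delta[d$ns_dummy == 0])
    m1 <- mean(d$delta[d$ns_dummy == 1])
    expect_equal(est$estimate[est$term == "alpha"], m0)
    expect_equal(est$estimate[est$term == "beta_ns"], m1 - m0)
    expect_equal(est$estimate[est$term == "alpha_plus_beta"], m1)
  }
})

test_that("degenerate all-zero differences give zero effects", {
  d <- simulate_differences(20, sd_participant = 0, sd_shop = 0, seed = 4)
  fit <- suppressWarnings(fit_first_difference(d))
  expect_equal(tidy(fit)$estimate, c(0, 0, 0))
})

test_that("the contrast identity alpha + beta = sum holds to machine precision", {
  d <- simulate_differences(80, effect_mtl = 1.16 - 1.09, effect_ns = 0.31,
                            seed = 12)
  est <- tidy(fit_first_difference(d))
  expect_identical(est$estimate[3], est$estimate[1] + est$estimate[2])
})

test_that("cluster-robust covariance matches a hand-written sandwich", {
  d <- simulate_differences(60, effect_mtl = 0.5, effect_ns = 1, seed = 9)
  fit <- fit_first_difference(d)
  X <- cbind(1, d$ns_dummy)
  u <- d$delta - X %*% coef(fit$model)
  bread <- solve(crossprod(X))
  meat <- Reduce(`+`, lapply(split(seq_len(nrow(d)), d$participant_id),
                             function(idx) {
    s <- crossprod(X[idx, , drop = FALSE], u[idx])
    s %*% t(s)
  }))
  G <- dplyr::n_distinct(d$participant_id); N <- nrow(d); k <- 2
  V <- G / (G - 1) * (N - 1) / (N - k) * bread %*% meat %*% bread
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)
})

test_that("estimates are invariant to row order and participant relabeling", {
  d <- simulate_differences(50, effect_mtl = 0.4, effect_ns = 0.9, seed = 3)
  base <- tidy(fit_first_difference(d))
  perm <- d[sample.int(nrow(d)), ]
  expect_equal(tidy(fit_first_difference(perm)), base)
  relab <- dplyr::mutate(d, participant_id = paste0("Z", participant_id))
  expect_equal(tidy(fit_first_difference(relab))$estimate, base$estimate)
  expect_equal(tidy(fit_first_difference(relab))$std.error, base$std.error)
})

test_that("single-condition input is a rank-deficiency error", {
  d <- simulate_differences(20, seed = 5)
  expect_error(fit_first_difference(d[d$ns_dummy == 1, ]),
               class = "nutricart_rank_error")
  expect_error(fit_first_difference(d[0, ]), class = "nutricart_data_error")
})

test_that("moderator fit reproduces cell means in a balanced design", {
  # 2x2 balanced cells with known means, two obs per participant
  cell_mean <- c(`00` = 1, `01` = 2, `10` = 4, `11` = 7)  # m, ns
  d <- tidyr::expand_grid(i = 1:40, ns_dummy = 0:1) |>
    dplyr::mutate(participant_id = sprintf("P%02d", i),
                  m = as.integer(i <= 20),
                  delta = cell_mean[paste0(m, ns_dummy)])
  fit <- suppressWarnings(fit_moderator(d, "m"))
  est <- tidy(fit)
  get <- function(term) est$estimate[est$term == term]
  expect_equal(get("alpha"), 1)                 # cell (m=0, ns=0)
  expect_equal(get("beta_ns"), 1)               # 2 - 1
  expect_equal(get("beta_m"), 3)                # 4 - 1
  expect_equal(get("beta_int"), 7 - 2 - 4 + 1)
  expect_equal(get("beta_m_plus_int"), 7 - 2)  # moderator shift under NS
  expect_error(fit_moderator(dplyr::mutate(d, m = 1L), "m"),
               class = "nutricart_rank_error")
})

test_that("a moderator independent of the outcome is centred on zero", {
  set.seed(77)
  bms <- replicate(150, {
    d <- simulate_differences(60, seed = sample.int(1e6, 1))
    d$m <- rbinom(nrow(d), 1, 0.5)
    tidy(fit_moderator(d, "m"))$estimate[4]
  })
  expect_lt(abs(mean(bms)), 3 * sd(bms) / sqrt(length(bms)))
})

test_that("median splits send values at the median to one", {
  s <- dplyr::bind_rows(
    mk_summaries("P1", c("Control", "MTL", "NS"), 1:3,
                 mood = 2, hunger = 5),
    mk_summaries("P2", c("Control", "MTL", "NS"), 1:3,
                 mood = 4, hunger = 3),
    mk_summaries("P3", c("Control", "MTL", "NS"), 1:3,
                 mood = 6, hunger = 1))
  d <- build_differences(s, "y")
  # cohort mood median 4: values 4 and 6 are "happy"
  expect_equal(d$happy[d$participant_id == "P1"], c(0, 0))
  expect_equal(d$happy[d$participant_id == "P2"], c(1, 1))
  expect_equal(d$happy[d$participant_id == "P3"], c(1, 1))
  # hunger median 3: 5 and 3 are "hungry", 1 is not
  expect_equal(unique(d$hungry[d$participant_id == "P2"]), 1)
  expect_equal(unique(d$hungry[d$participant_id == "P3"]), 0)
})

test_that("stratified totals add up and AHEI is refused per stratum", {
  catalog <- toy_catalog()
  participants <- toy_participants(c("P1", "P2", "P3"))
  orders <- dplyr::bind_rows(
    shop_lines("P1", 1, "Control", c("VEG", "CHOC", "SODA"), c(5, 3, 2)),
    shop_lines("P1", 2, "MTL", c("VEG", "WATER"), c(6, 4)),
    shop_lines("P1", 3, "NS", c("CHOC", "SODA", "WATER"), c(2, 3, 1)),
    shop_lines("P2", 1, "Control", c("CHOC", "SODA"), c(8, 5)),
    shop_lines("P2", 2, "MTL", c("VEG", "SODA"), c(2, 6)),
    shop_lines("P2", 3, "NS", c("VEG", "CHOC"), c(3, 2)),
    shop_lines("P3", 1, "Control", c("WATER", "VEG"), c(5, 5)),
    shop_lines("P3", 2, "MTL", c("CHOC", "WATER"), c(4, 2)),
    shop_lines("P3", 3, "NS", c("SODA", "VEG"), c(4, 4)))
  all_s <- score_baskets(orders, catalog, participants)
  food_ids <- catalog$product_id[catalog$category == "food"]
  foods <- score_baskets(dplyr::filter(orders, product_id %in% food_ids),
                         catalog, participants)
  bevs <- score_baskets(dplyr::filter(orders, !product_id %in% food_ids),
                        catalog, participants)
  key <- c("participant_id", "shop_index")
  merged <- dplyr::left_join(
    dplyr::select(all_s, dplyr::all_of(key), all_kcal = total_energy_kcal),
    dplyr::select(foods, dplyr::all_of(key), food_kcal = total_energy_kcal),
    by = key) |>
    dplyr::left_join(
      dplyr::select(bevs, dplyr::all_of(key), bev_kcal = total_energy_kcal),
      by = key) |>
    tidyr::replace_na(list(food_kcal = 0, bev_kcal = 0))
  expect_equal(merged$all_kcal, merged$food_kcal + merged$bev_kcal)

  expect_error(run_crossover(orders, catalog, participants,
                             outcomes = "modified_ahei", stratum = "foods"),
               class = "nutricart_unsupported_outcome_error")
  # stratum = all equals the unstratified pipeline
  res_all <- run_crossover(orders, catalog, participants,
                           outcomes = "avg_nutriscore", stratum = "all")
  direct <- tidy(fit_first_difference(
    build_differences(all_s, "avg_nutriscore")))
  expect_equal(res_all$estimate, direct$estimate)
})

test_that("sample size follows the paired normal approximation", {
  expect_equal(sample_size_crossover(0.30, 0.05, 0.90, 3), 151L)
  expect_equal(sample_size_crossover(0.30, 0.05, 0.90, 1), 117L)
  # doubling the effect size quarters the requirement (up to ceiling)
  n1 <- sample_size_crossover(0.2, 0.05, 0.9, 1)
  n2 <- sample_size_crossover(0.4, 0.05, 0.9, 1)
  expect_lte(n2, ceiling(n1 / 4) + 1)
  expect_error(sample_size_crossover(-1), class = "nutricart_domain_error")
})

test_that("implied coronary-artery-disease reduction is a linear scaling", {
  expect_equal(implied_cad_reduction(1.16, 21), 2.4)
  expect_equal(implied_cad_reduction(10, 21), 21.0)
  expect_equal(implied_cad_reduction(0, 21), 0.0)
})
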