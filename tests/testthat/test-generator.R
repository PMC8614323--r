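test_that("herd rosters honour the configured counts and structure", {
  cfg <- small_config()
  cfg$n_females <- 137L; cfg$n_males <- 128L
  herd <- generate_herd(cfg)
  expect_equal(nrow(herd), 265L)
  expect_equal(sum(herd$sex == "f"), 137L)
  # single-sex groups
  for (g in unique(herd$group_id)) {
    expect_equal(length(unique(herd$sex[herd$group_id == g])), 1L)
  }
  # sex-specific age bounds
  expect_true(all(herd$age_years[herd$sex == "f"] >= 1 &
                    herd$age_years[herd$sex == "f"] <= 21))
  expect_true(all(herd$age_years[herd$sex == "m"] <= 15))
  expect_true(all(herd$body_weight_kg > 0))
})

test_that("latent rank decouples from body traits when the correlation is 0", {
  cfg <- generator_config(n_females = 400L, n_males = 400L,
                          rank_trait_correlation = 0, seed = 8)
  herd <- generate_herd(cfg)
  expect_lt(abs(cor(herd$latent_rank, herd$body_weight_kg)), 0.1)
  cfg2 <- generator_config(n_females = 400L, n_males = 400L,
                           rank_trait_correlation = 0.8, seed = 8)
  herd2 <- generate_herd(cfg2)
  expect_gt(cor(herd2$latent_rank, herd2$age_years), 0.3)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config(seed = 99)
  expect_identical(generate_herd(cfg), generate_herd(cfg))
  expect_identical(generate_weather(cfg), generate_weather(cfg))
  h <- generate_herd(cfg); w <- generate_weather(cfg)
  expect_identical(simulate_monitoring(h, w, cfg),
                   simulate_monitoring(h, w, cfg))
  expect_identical(simulate_pregnancy_panel(cfg),
                   simulate_pregnancy_panel(cfg))
  expect_identical(simulate_hierarchy_panel(cfg),
                   simulate_hierarchy_panel(cfg))
  # a different seed changes the draws
  cfg2 <- small_config(seed = 100)
  expect_false(identical(generate_weather(cfg), generate_weather(cfg2)))
  expect_false(identical(generate_herd(cfg), generate_herd(cfg2)))
})

test_that("undersized configurations are rejected", {
  expect_error(generator_config(n_females = 3L, n_males = 30L),
               "at least 2 animals")
  expect_error(generator_config(n_groups_per_sex = 7L), "\\[2, 6\\]")
  expect_error(generator_config(rank_trait_correlation = 1.5), "\\[-1, 1\\]")
  expect_error(generator_config(interaction_steepness = 0), "> 0")
})

test_that("weather covers July-August daily with year-level shifts", {
  cfg <- small_config()
  cfg$n_years <- 1L
  w <- generate_weather(cfg)
  expect_equal(nrow(w), 62L) # 31 July + 31 August days
  expect_true(all(format(w$date, "%m") %in% c("07", "08")))
  expect_true(all(w$Hr >= 0 & w$Hr <= 100))
  expect_true(all(w$W >= 0) && all(w$SR >= 0))

  # zero SDs and amplitudes give a constant series at the means
  cfg0 <- small_config()
  cfg0$weather_params <- list(
    T = list(mean = 24, year_sd = 0, day_sd = 0, amp = 0),
    Hr = list(mean = 50, year_sd = 0, day_sd = 0),
    W = list(mean = 2, year_sd = 0, day_sd = 0),
    SR = list(mean = 25, year_sd = 0, day_sd = 0, amp = 0)
  )
  w0 <- generate_weather(cfg0)
  expect_true(all(w0$T == 24) && all(w0$Hr == 50) && all(w0$SR == 25))

  # seasonal heat stress differs among years through the year shifts
  tab <- seasonal_thiws_table(generate_weather(small_config()))
  expect_gt(stats::sd(tab$thiws_mean), 0)
})

test_that("interaction outcomes follow the rank-difference sigmoid", {
  cfg <- small_config()
  cfg$interactions_per_dyad <- 600
  equal <- data.frame(id = c("A", "B"), sex = "f", group_id = "g1",
                      latent_rank = c(0.5, 0.5))
  rec <- simulate_interactions(equal, cfg)
  expect_equal(mean(rec$aggressor_id == "A"), 0.5, tolerance = 0.06)

  cfg$interaction_steepness <- 60 # near-deterministic outcomes
  strict <- data.frame(id = c("A", "B"), sex = "f", group_id = "g1",
                       latent_rank = c(2, -2))
  rec2 <- simulate_interactions(strict, cfg)
  expect_true(all(rec2$aggressor_id == "A"))
  expect_true(all(rec2$behaviour %in% names(peltbite:::interaction_behaviours)))

  lone <- data.frame(id = "A", sex = "f", group_id = "g1", latent_rank = 0)
  expect_warning(simulate_interactions(lone, cfg), "fewer than 2")
})

test_that("a strict latent order is recovered through Combi1 and I&SI", {
  cfg <- small_config(seed = 3)
  cfg$interactions_per_dyad <- 650 # ~2000 interactions over 3 dyads
  cfg$interaction_steepness <- 2
  roster <- data.frame(id = c("A", "B", "C"), sex = "f", group_id = "g1",
                       latent_rank = c(1.5, 0, -1.5))
  rec <- simulate_interactions(roster, cfg)
  m <- build_dominance_matrix(rec, roster$id)
  sc <- combi1(m)
  expect_equal(sc$id[order(-sc$combi1)], c("A", "B", "C"))
  rk <- isi_order(m, seed = 1)
  expect_equal(rk$id, c("A", "B", "C"))
})

test_that("monitoring panels carry valid classes, groups and heat stress", {
  cfg <- small_config()
  herd <- generate_herd(cfg); w <- generate_weather(cfg)
  mon <- simulate_monitoring(herd, w, cfg)
  expect_true(all(mon$pelt_class >= 1 & mon$pelt_class <= 5))
  expect_true(all(mon$pelt_class %in% seq(1, 5, by = 0.25)))
  expect_true(all(is.finite(mon$thiws)))
  expect_true(all(mon$group_size >= 1))
  # group size is the count of animals sharing the group at the event
  one <- mon[mon$doy == mon$doy[1] & mon$year == mon$year[1], ]
  counts <- table(one$group_id)
  expect_equal(unname(counts[one$group_id]), one$group_size,
               ignore_attr = TRUE)
  # discretization is monotone in the latent response
  ord <- order(mon$pelt_latent)
  expect_true(all(diff(mon$pelt_class[ord]) >= 0))
  expect_s3_class(attr(mon, "basis"), "poly_basis")
})

test_that("a noiseless configuration produces the bare intercept", {
  cfg <- small_config()
  cfg$coefficients$population[] <- 0
  cfg$coefficients$population[["(Intercept)"]] <- 1.35
  cfg$re_sd$population[] <- 0
  cfg$residual_sd[["population"]] <- 0
  herd <- generate_herd(cfg); w <- generate_weather(cfg)
  mon <- simulate_monitoring(herd, w, cfg)
  expect_true(all(mon$pelt_latent == 1.35))
  expect_true(all(mon$pelt_class == snap_class(1.35)))
})

test_that("unknown coefficient names are a configuration error", {
  cfg <- small_config()
  cfg$coefficients$population <- c(cfg$coefficients$population,
                                   bogus.1 = 2)
  herd <- generate_herd(cfg); w <- generate_weather(cfg)
  expect_error(simulate_monitoring(herd, w, cfg), "configuration error")
})

test_that("component variances match configuration by direct decomposition", {
  # uncalibrated panel: the latent response is exactly the configured
  # linear predictor plus components with the configured SDs, so a plain
  # moment decomposition (no model fitting) must recover them
  cfg <- generator_config(seed = 4, calibrate = FALSE)
  herd <- generate_herd(cfg); w <- generate_weather(cfg)
  mon <- simulate_monitoring(herd, w, cfg)
  expect_gt(nrow(mon), 5000L)
  beta <- cfg$coefficients$population
  terms <- setdiff(names(beta), "(Intercept)")
  d <- population_design(mon, attr(mon, "basis"))
  eta <- beta[["(Intercept)"]] + as.numeric(as.matrix(d[terms]) %*%
                                              beta[terms])
  r <- mon$pelt_latent - eta
  # residual variance from the double-centered remainder
  r_e <- r - stats::ave(r, mon$animal_id) - stats::ave(r, mon$year) +
    mean(r)
  sd_e_hat <- stats::sd(r_e)
  expect_equal(sd_e_hat, cfg$residual_sd[["population"]], tolerance = 0.1)
  # animal variance from animal means of the year-adjusted remainder,
  # minus the residual noise carried into a mean of n_i events
  r_a <- r - stats::ave(r, mon$year)
  m_a <- tapply(r_a, mon$animal_id, mean)
  n_a <- tapply(r_a, mon$animal_id, length)
  v_a <- stats::var(m_a) - sd_e_hat^2 * mean(1 / n_a)
  expect_equal(sqrt(v_a), unname(cfg$re_sd$population["animal_id"]),
               tolerance = 0.1)
  # year variance from raw year means (animal effects average out over
  # the many animals active per year; correct for both noise sources)
  m_y <- tapply(r, mon$year, mean)
  n_y <- tapply(r, mon$year, length)
  n_anim_y <- tapply(mon$animal_id, mon$year,
                     function(a) length(unique(a)))
  v_y <- stats::var(m_y) - sd_e_hat^2 * mean(1 / n_y) -
    v_a * mean(1 / n_anim_y)
  expect_equal(sqrt(max(v_y, 0)), unname(cfg$re_sd$population["year"]),
               tolerance = 0.15)
})
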