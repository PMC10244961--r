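test_that("generated landscapes round-trip through the stratifier", {
  cfg <- scenario_config(n_sites = c(high = 10, low = 10, none = 10),
                         n_species = 2, first_year = 2000, last_year = 2003,
                         seed = 31)
  land <- gen_landscape(cfg)
  cls <- classify_sites(land$cover)
  expect_equal(sum(cls$region == "high"), 10)
  expect_equal(sum(cls$region == "low"), 10)
  expect_equal(sum(cls$region == "none"), 10)
  expect_equal(sum(cls$region == "excluded"), 0)
  # classifications agree with the generator's intent site by site
  m <- merge(cls, land$sites, by = "site")
  expect_equal(as.character(m$region.x), m$region.y)
  # none-region cells always have zero cropland in both epochs
  none_cover <- land$cover[land$cover$class == "cropland" &
                             land$cover$site %in%
                             land$sites$site[land$sites$region == "none"], ]
  expect_true(all(none_cover$percent == 0))
})

test_that("violation cells are excluded with the right reasons", {
  cfg <- scenario_config(n_sites = c(high = 5, low = 5, none = 5),
                         n_species = 2, first_year = 2000, last_year = 2003,
                         n_violation_change = 5, n_violation_class = 3,
                         seed = 32)
  cls <- classify_sites(gen_landscape(cfg)$cover)
  expect_equal(sum(cls$exclusion_reason == "cover_change", na.rm = TRUE), 5)
  expect_equal(sum(cls$exclusion_reason == "incomparable_class",
                   na.rm = TRUE), 3)
  expect_equal(sum(cls$region == "excluded"), 8)
})

test_that("dynamics follow the requested growth and site-effect structure", {
  cfg0 <- scenario_config(n_sites = c(high = 8, low = 8, none = 8),
                          n_species = 2, first_year = 2000, last_year = 2009,
                          growth = c(high = 0, low = 0, none = 0),
                          seed = 33)
  tr <- gen_dynamics(cfg0)
  # zero growth: expected occupancy constant across years
  expect_true(all(abs(sweep(tr$psi_expected, c(1, 2),
                            tr$psi_expected[, , 1])) < 1e-10))
  # sigma_u = 0: every site in a region shares the same occupancy probability
  cfg1 <- scenario_config(n_sites = c(high = 8, low = 8, none = 8),
                          n_species = 1, first_year = 2000, last_year = 2004,
                          sigma_u = 0, species_sd = 0, seed = 34)
  tr1 <- gen_dynamics(cfg1)
  expect_true(all(tr1$u == 0))
  expect_equal(stats::plogis(tr1$b[1, , 1]), cfg1$psi0,
               ignore_attr = TRUE, tolerance = 1e-8)
  # unattainable trajectory errors
  cfg2 <- scenario_config(n_sites = c(high = 4, low = 4, none = 4),
                          n_species = 1, first_year = 2000, last_year = 2019,
                          psi0 = c(high = 0.5, low = 0.5, none = 0.5),
                          growth = c(high = 5, low = 0, none = 0),
                          seed = 35)
  expect_error(gen_dynamics(cfg2), "outside")
})

test_that("realised occupancy tracks the requested growth at large n", {
  cfg <- scenario_config(n_sites = c(high = 4000, low = 4, none = 4),
                         n_species = 1, first_year = 2000, last_year = 2001,
                         growth = c(high = -20, low = 0, none = 0),
                         species_sd = 0, seed = 36)
  tr <- gen_dynamics(cfg)
  ratio <- tr$occ_true[1, "high", 2] / tr$occ_true[1, "high", 1]
  # binomial error on 4000 sites at psi ~ 0.4 is ~ 0.008 per year; 4 sd
  expect_equal(ratio, 0.8, tolerance = 0.05)
})

test_that("recording emulates detection with list-length effort", {
  # near-perfect detection: naive occupancy equals the latent states on
  # every site-year that received at least one visit
  cfg <- scenario_config(n_sites = c(high = 10, low = 10, none = 10),
                         n_species = 3, first_year = 2000, last_year = 2003,
                         p_single = 0.999999, beta1 = 0, beta2 = 0,
                         visit_rate = 4, seed = 37)
  sim <- simulate_scenario(cfg)
  v <- build_visits(standardize_records(sim$records, 2000, 2003), 2000)
  for (sp in sim$truth$species) {
    h <- detection_history(v, sp)
    naive <- tapply(h$detected, list(h$site, h$year_index), max)
    for (s in rownames(naive)) for (t in colnames(naive)) {
      if (!is.na(naive[s, t])) {
        expect_equal(unname(naive[s, t]),
                     unname(sim$truth$z[s, as.integer(t) + 1L, sp]))
      }
    }
  }
  # p = 0 emits no focal-species records (fillers still document visits)
  cfg0 <- scenario_config(n_sites = c(high = 5, low = 5, none = 5),
                          n_species = 3, first_year = 2000, last_year = 2001,
                          p_single = 1e-12, beta1 = 0, beta2 = 0, seed = 38)
  sim0 <- simulate_scenario(cfg0)
  expect_false(any(sim0$records$species %in% sim0$truth$species))
})

test_that("empirical detection frequency matches the configured probability", {
  cfg <- scenario_config(n_sites = c(high = 60, low = 4, none = 4),
                         n_species = 1, first_year = 2000, last_year = 2019,
                         psi0 = c(high = 0.8, low = 0.5, none = 0.5),
                         growth = c(high = 0, low = 0, none = 0),
                         sigma_u = 0, species_sd = 0,
                         p_single = 0.3, beta1 = 0, beta2 = 0,
                         visit_rate = 8, seed = 39)
  sim <- simulate_scenario(cfg)
  v <- build_visits(standardize_records(sim$records, 2000, 2019), 2000)
  h <- detection_history(v, "sp_01")
  occupied <- mapply(function(s, t) sim$truth$z[s, t + 1L, 1] == 1L,
                     h$site, h$year_index)
  n_occ <- sum(occupied)
  expect_gt(n_occ, 2000)
  rate <- mean(h$detected[occupied])
  se <- sqrt(0.3 * 0.7 / n_occ)
  expect_equal(rate, 0.3, tolerance = 5 * se / 0.3)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- scenario_config(n_sites = c(high = 6, low = 6, none = 6),
                         n_species = 2, first_year = 2000, last_year = 2002,
                         seed = 40)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$cover, s2$cover)
  expect_identical(s1$truth$z, s2$truth$z)
  expect_error(scenario_config(n_sites = c(high = 1, low = 1, none = 1),
                               n_species = 1), "seed")
})

test_that("the truth ledger recomputes group growth from latent states", {
  fx <- tiny_scenario()
  tg <- true_group_growth(fx$sim$truth)
  expect_named(tg$group_growth, c("high", "low", "none"))
  # the generating truth reproduces the configured growth exactly
  expect_equal(unname(tg$group_growth_expected),
               unname(fx$cfg$growth), tolerance = 1e-6)
  expect_equal(tg$effect_size_high_low,
               tg$group_growth[["high"]] - tg$group_growth[["low"]])
  # oracle: recompute from z directly
  z <- fx$sim$truth$z
  reg <- fx$sim$truth$sites$region
  occ1 <- sapply(dimnames(z)[[3]], function(sp)
    mean(z[reg == "high", 1, sp]))
  occT <- sapply(dimnames(z)[[3]], function(sp)
    mean(z[reg == "high", dim(z)[2], sp]))
  fl <- 1 / (2 * sum(reg == "high"))
  oracle <- growth_rate(exp(mean(log(pmax(occ1, fl)))),
                        exp(mean(log(pmax(occT, fl)))), dim(z)[2] - 1)
  expect_equal(tg$group_growth[["high"]], oracle)
})
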