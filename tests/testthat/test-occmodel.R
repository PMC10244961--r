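test_that("state linear predictor uses only the site's own region", {
  inst <- random_instance(4, 3, 10, seed = 1)
  d <- inst$data; p <- inst$params
  p0 <- p; p0$b[] <- 0; p0$u[] <- 0
  expect_equal(stats::plogis(state_logit(p0, d, site = 1, year = 0)), 0.5)
  p1 <- p0; p1$b[1, 2] <- 1; p1$u[1] <- -1
  i_high <- which(d$region == 1L)[1]
  expect_equal(state_logit(p1, d, site = i_high, year = 1),
               1 + p1$u[i_high])
  # changing a year effect of a region with no focal site leaves psi alone
  sr <- data.frame(site = sprintf("s%d", 1:3), region = "high")
  hist <- data.frame(site = sr$site, year_index = 0L, datatype = "single",
                     detected = c(1L, 0L, 1L))
  d1 <- occ_model_data(hist, sr, n_years = 2)
  pp <- list(b = matrix(stats::rnorm(2), 1, 2), u = stats::rnorm(3))
  eta1 <- state_logit(pp, d1)
  oracle <- outer(pp$u, pp$b[1, ], `+`)
  expect_equal(eta1, oracle, ignore_attr = TRUE)
})

test_that("observation predictor applies list-length offsets", {
  p <- list(a = c(0, -1), beta1 = 1, beta2 = 2.5)
  expect_equal(stats::plogis(obs_logit(p, 0, "single")), 0.5)
  expect_equal(obs_logit(p, 0, "short"), 1)
  expect_equal(obs_logit(p, 1, "long"), 1.5)
  # monotone in effort category when beta2 > beta1 > 0
  ps <- stats::plogis(obs_logit(p, 0, c("single", "short", "long")))
  expect_true(all(diff(ps) > 0))
  expect_error(obs_logit(p, 0, "weird"), "datatype")
})

test_that("augmented kernel rejects z = 0 at a detection and sums to the
           marginalised kernel", {
  inst <- random_instance(2, 2, 3, seed = 3)
  d <- inst$data; p <- inst$params
  z0 <- matrix(0L, 2, 2)
  expect_identical(log_posterior_kernel(c(p, list(z = z0)), d,
                                        form = "augmented"), -Inf)
  pri <- occ_priors()
  lp_marg <- log_posterior_kernel(p, d, pri, form = "marginalized")
  lp_enum <- enumerate_augmented(p, d, pri)
  expect_equal(lp_marg, lp_enum, tolerance = 1e-10)
  expect_identical(log_posterior_kernel(
    within(p, beta1 <- NaN), d, pri), -Inf)
})

test_that("marginalised kernel matches a naive per-cell oracle", {
  # naive oracle: loop over cells, mix over z with plain dbinom products
  naive_ll <- function(p, d) {
    ll <- 0
    for (i in seq_len(d$n_sites)) {
      for (t in seq_len(d$n_years)) {
        vs <- which(d$visit_site == i & d$visit_year == t)
        if (length(vs) == 0) next
        psi <- stats::plogis(p$b[d$region[i], t] + p$u[i])
        pv <- stats::plogis(p$a[t] + p$beta1 * (d$visit_dt[vs] == 2) +
                              p$beta2 * (d$visit_dt[vs] == 3))
        lik1 <- psi * prod(stats::dbinom(d$y[vs], 1, pv))
        lik0 <- (1 - psi) * as.numeric(all(d$y[vs] == 0))
        ll <- ll + log(lik1 + lik0)
      }
    }
    ll
  }
  inst <- random_instance(3, 2, 8, seed = 9)
  d <- inst$data; p <- inst$params
  pri <- occ_priors()
  # shift b: the kernel difference must equal the oracle likelihood
  # difference plus the first-year prior shift (rw increments are unchanged)
  q <- p
  q$b <- p$b + 0.3
  dprior <- sum(stats::dnorm(q$b[, 1], 0, 10, log = TRUE)) -
    sum(stats::dnorm(p$b[, 1], 0, 10, log = TRUE))
  lp_p <- log_posterior_kernel(p, d, pri, form = "marginalized")
  lp_q <- log_posterior_kernel(q, d, pri, form = "marginalized")
  expect_equal(lp_q - lp_p, (naive_ll(q, d) - naive_ll(p, d)) + dprior,
               tolerance = 1e-10)
})

test_that("split-chain Rhat separates mixed from shifted chains", {
  set.seed(11)
  same <- cbind(stats::rnorm(3000), stats::rnorm(3000))
  expect_lt(gelman_rubin(same), 1.05)
  shifted <- cbind(stats::rnorm(200), stats::rnorm(200, 100))
  expect_gt(gelman_rubin(shifted), 1.1)
  # formula oracle on a fixed small matrix
  m <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 6))
  half <- 2
  sub <- cbind(m[1:2, ], m[3:4, ])
  W <- mean(apply(sub, 2, stats::var))
  B <- half * stats::var(colMeans(sub))
  expect_equal(gelman_rubin(m),
               sqrt(((half - 1) / half * W + B / half) / W))
  expect_warning(r <- gelman_rubin(cbind(rep(1, 10), rep(1, 10))),
                 "undefined")
  expect_true(is.na(r))
  # vector + chain-id interface
  x <- c(stats::rnorm(100), stats::rnorm(100))
  expect_equal(gelman_rubin(x, chain = rep(1:2, each = 100)),
               gelman_rubin(matrix(x, 100)))
})

test_that("random-walk prior governs year-effect increments without data", {
  # one site, one visit that carries no information (detection fixed ~0),
  # so the posterior of b is its prior: increments have sd sigma_rw
  hist <- data.frame(site = "s1", year_index = 0L, datatype = "single",
                     detected = 0L)
  d <- occ_model_data(hist, data.frame(site = "s1", region = "high"),
                      n_years = 8)
  pri <- occ_priors(b0 = list(dist = "normal", mean = 0, sd = 1))
  dr <- sample_posterior(
    d, chains = 2, iterations = 6000, burnin = 1000, thin = 2, seed = 4,
    priors = pri,
    fixed = list(u = 0, a = -20, beta1 = 0, beta2 = 0, sigma_u = 1,
                 sigma_rw = 0.7))
  inc <- apply(dr$b[, 1, ], 1, diff)               # 7 x draws
  expect_lt(abs(sd(as.vector(inc)) - 0.7), 0.05)
  expect_lt(abs(mean(inc)), 0.1)
  expect_lt(abs(sd(dr$b[, 1, 1]) - 1), 0.15)       # anchor prior
})

test_that("sampling is reproducible for a fixed seed and differs across seeds", {
  fx <- tiny_scenario()
  h <- detection_history(fx$visits, "sp_03")
  d <- occ_model_data(h, fx$site_regions, n_years = 6)
  d1 <- sample_posterior(d, chains = 2, iterations = 300, burnin = 100,
                         thin = 2, seed = 21)
  d2 <- sample_posterior(d, chains = 2, iterations = 300, burnin = 100,
                         thin = 2, seed = 21)
  expect_identical(d1$b, d2$b)
  expect_identical(d1$occ, d2$occ)
  d3 <- sample_posterior(d, chains = 2, iterations = 300, burnin = 100,
                         thin = 2, seed = 22)
  expect_false(identical(d1$b, d3$b))
  expect_equal(length(d1$chain), 2 * floor(200 / 2))
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  fx <- tiny_scenario()
  h <- detection_history(fx$visits, "sp_02")
  d <- occ_model_data(h, fx$site_regions, n_years = 6)
  dr <- sample_posterior(d, chains = 3, iterations = 6000, burnin = 2000,
                         thin = 4, seed = 3)
  mstr <- "model{
   for (i in 1:nsite){ u[i] ~ dnorm(0, tau.u)
    for (t in 1:nyear){ logit(psi[i,t]) <- b[region[i],t] + u[i]
     z[i,t] ~ dbern(psi[i,t]) }}
   for (v in 1:nvisit){ logit(p[v]) <- a[year[v]] + beta1*sh[v] + beta2*lg[v]
    y[v] ~ dbern(p[v]*z[site[v],year[v]]) }
   for (r in 1:nregion){ b[r,1] ~ dnorm(0, 0.01)
    for (t in 2:nyear){ b[r,t] ~ dnorm(b[r,t-1], tau.rw) }}
   for (t in 1:nyear){ a[t] ~ dnorm(mu.a, tau.a) }
   mu.a ~ dnorm(0, 0.01)
   sigma.a ~ dunif(0,5); tau.a <- pow(sigma.a,-2)
   beta1 ~ dnorm(0, 0.01); beta2 ~ dnorm(0, 0.01)
   sigma.u ~ dunif(0,5); tau.u <- pow(sigma.u,-2)
   sigma.rw ~ dunif(0,5); tau.rw <- pow(sigma.rw,-2)
  }"
  dat <- list(nsite = d$n_sites, nyear = d$n_years, nvisit = d$n_visits,
              nregion = d$n_regions, region = d$region, site = d$visit_site,
              year = d$visit_year, sh = as.numeric(d$visit_dt == 2),
              lg = as.numeric(d$visit_dt == 3), y = d$y)
  jm <- rjags::jags.model(
    textConnection(mstr), data = dat,
    inits = list(z = matrix(1L, d$n_sites, d$n_years),
                 .RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
    n.chains = 2, quiet = TRUE)
  update(jm, 2000)
  js <- rjags::jags.samples(jm, c("z", "beta1", "beta2", "sigma.u"),
                            n.iter = 4000, thin = 4)
  occ_j <- t(vapply(seq_len(d$n_regions), function(r)
    apply(js$z[d$region == r, , , , drop = FALSE], 2, mean),
    numeric(d$n_years)))
  occ_o <- apply(dr$occ, c(2, 3), mean)
  expect_lt(max(abs(occ_j - occ_o)), 0.05)
  expect_equal(mean(dr$beta[, 1]), mean(js$beta1), tolerance = 0.25)
  expect_equal(mean(dr$beta[, 2]), mean(js$beta2), tolerance = 0.25)
  expect_equal(mean(dr$sigma_u), mean(js$sigma.u), tolerance = 0.2)
})

test_that("convergence report and filter flag unstable or missing Rhats", {
  fx <- tiny_scenario()
  h <- detection_history(fx$visits, "sp_01")
  d <- occ_model_data(h, fx$site_regions, n_years = 6)
  dr <- sample_posterior(d, chains = 2, iterations = 1200, burnin = 600,
                         thin = 2, seed = 8)
  rep <- convergence_report(dr)
  expect_true(all(c("occ[high,first]", "occ[high,last]") %in% rep$quantity))
  # split Rhat is bounded below by sqrt((n-1)/n), not exactly 1
  expect_true(all(rep$rhat > 0.99, na.rm = TRUE))

  reports <- data.frame(species = c("a", "b", "c"),
                        rhat_first = c(1.05, 1.05, NA),
                        rhat_last = c(1.08, 1.2, 1.0))
  expect_message(cf <- convergence_filter(reports), "flagged")
  expect_equal(cf$retained, c(TRUE, FALSE, FALSE))
  expect_equal(cf$flagged, c(FALSE, FALSE, TRUE))
  empty <- convergence_filter(data.frame(species = character(),
                                         rhat_first = numeric(),
                                         rhat_last = numeric()))
  expect_equal(nrow(empty), 0)
})
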