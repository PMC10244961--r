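# Hierarchical occupancy-detection model with region-specific year effects.
#
# State model:      z[i,t] ~ Bernoulli(psi[i,t])
#                   logit(psi[i,t]) = b[region(i), t] + u[i]
# Observation:      y[i,t,v] ~ Bernoulli(p[t,v] * z[i,t])
#                   logit(p[t,v]) = a[t] + beta1*[short list] + beta2*[long list]
# Priors:           b[r,1] wide normal (or logistic); b[r,t] ~ N(b[r,t-1], sigma_rw^2)
#                   u[i] ~ N(0, sigma_u^2); a, beta wide normal;
#                   sigma_u, sigma_rw ~ Uniform(0, max) or half-normal.

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x)), branch-free
  ax <- abs(x)
  (x + ax) * 0.5 + log1p(exp(-ax))
}

group_sums <- function(x, g) {
  # sums of x over precomputed sorted groups: g$ord sorts by group,
  # g$ends marks the last position of each group in the sorted order
  cs <- cumsum(x[g$ord])
  diff(c(0, cs[g$ends]))
}

make_grouper <- function(group) {
  ord <- order(group)
  sorted <- group[ord]
  ends <- c(which(sorted[-1L] != sorted[-length(sorted)]), length(sorted))
  list(ord = ord, ends = ends, labels = sorted[ends])
}

#' Assemble model data from a detection history and site classifications
#'
#' @param history output of [detection_history()]: one row per visit with
#'   `site`, `year_index`, `datatype`, `detected`.
#' @param site_regions data.frame with columns `site` and `region`, or a
#'   named character vector mapping site to region. Every site in `history`
#'   must be classified; sites labelled `excluded` are not allowed here
#'   (drop their visits first, see [species_visit_join()]).
#' @param n_years number of years in the study window; defaults to
#'   `max(year_index) + 1`.
#' @return an object of class `occ_data`: indexed visit arrays plus per-site
#'   region labels and precomputed site-year lookup tables.
#' @export
occ_model_data <- function(history, site_regions, n_years = NULL) {
  stopifnot(all(c("site", "year_index", "datatype", "detected") %in%
                  names(history)))
  if (nrow(history) == 0L) stop("empty detection history")
  if (is.data.frame(site_regions)) {
    site_regions <- stats::setNames(as.character(site_regions$region),
                                    site_regions$site)
  }
  sites <- sort(unique(as.character(history$site)))
  reg_chr <- site_regions[sites]
  if (anyNA(reg_chr)) {
    stop("unclassified site(s): ",
         paste(utils::head(sites[is.na(reg_chr)], 5), collapse = ", "))
  }
  if (any(reg_chr == "excluded")) {
    stop("visits at excluded sites must be dropped before model assembly")
  }
  canon <- c("high", "low", "none")
  levs <- c(intersect(canon, unique(reg_chr)),
            setdiff(sort(unique(reg_chr)), canon))
  if (is.null(n_years)) n_years <- max(history$year_index) + 1L
  if (any(history$year_index < 0L | history$year_index >= n_years)) {
    stop("year_index outside [0, n_years)")
  }
  dt <- as.integer(factor(as.character(history$datatype),
                          levels = c("single", "short", "long")))
  if (anyNA(dt)) stop("datatype must be single/short/long")

  visit_site <- match(as.character(history$site), sites)
  visit_year <- as.integer(history$year_index) + 1L
  n_sites <- length(sites)
  k <- (visit_year - 1L) * n_sites + visit_site   # column-major site-year cell

  y <- as.integer(history$detected)
  stopifnot(all(y %in% c(0L, 1L)))
  det_vec <- numeric(n_sites * n_years)
  tmp <- rowsum(y, k)
  det_vec[as.integer(rownames(tmp))] <- tmp
  nvis_vec <- numeric(n_sites * n_years)
  tmp <- rowsum(rep(1L, length(k)), k)
  nvis_vec[as.integer(rownames(tmp))] <- tmp

  structure(list(
    n_sites = n_sites, n_years = as.integer(n_years),
    n_visits = length(y), n_regions = length(levs),
    site_ids = sites,
    region = match(reg_chr, levs), region_levels = levs,
    visit_site = visit_site, visit_year = visit_year,
    visit_dt = dt, y = y, k = k,
    det_vec = det_vec, nvis_vec = nvis_vec
  ), class = "occ_data")
}

#' @export
print.occ_data <- function(x, ...) {
  cat("occupancy model data:", x$n_sites, "sites x", x$n_years, "years,",
      x$n_visits, "visits,", sum(x$y), "detections\n")
  cat("regions:", paste(sprintf("%s (%d sites)", x$region_levels,
                                tabulate(x$region, x$n_regions)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Linear predictor of the state model
#'
#' Only the year effect of the site's own region contributes:
#' `logit(psi[i,t]) = b[region(i), t] + u[i]`.
#'
#' @param params list with `b` (regions x years matrix) and `u` (per-site
#'   vector).
#' @param data an `occ_data` object.
#' @param site,year optional 1-based site index and 0-based year index; when
#'   omitted, the full sites x years logit matrix is returned.
#' @return logit-scale occupancy (scalar or matrix).
#' @export
state_logit <- function(params, data, site = NULL, year = NULL) {
  eta <- params$b[data$region, , drop = FALSE] + params$u
  if (is.null(site)) return(eta)
  eta[site, year + 1L]
}

#' Linear predictor of the observation model
#'
#' `logit(p) = a[t] + beta1 * [short list] + beta2 * [long list]`; the
#' single-species list is the reference category.
#'
#' @param params list with `a` (per-year vector), `beta1`, `beta2`.
#' @param year 0-based year index (vectorised).
#' @param datatype `"single"`, `"short"` or `"long"` (vectorised).
#' @return logit-scale detection probability.
#' @export
obs_logit <- function(params, year, datatype) {
  dt <- as.integer(factor(as.character(datatype),
                          levels = c("single", "short", "long")))
  if (anyNA(dt)) stop("datatype must be single/short/long")
  params$a[year + 1L] +
    params$beta1 * (dt == 2L) + params$beta2 * (dt == 3L)
}

#' Prior configuration for the occupancy-detection model
#'
#' The priors the model needs beyond the random-walk structure itself:
#' an anchor for the first-year effect, wide zero-mean normals on the
#' detection parameters, and half-width priors on the two standard
#' deviations. Defaults follow the usual weakly-informative convention for
#' occupancy models fitted to opportunistic records.
#'
#' @param b0 prior on the first-year effect per region:
#'   `list(dist = "normal", mean, sd)` or `list(dist = "logistic")`
#'   (standard logistic, i.e. uniform on the occupancy scale).
#' @param a prior on detection year effects. The default,
#'   `structure = "hierarchical"`, draws `a_t ~ N(mu_a, sigma_a^2)` with
#'   `mu_a ~ N(mean, sd^2)` and a half-width prior on `sigma_a`
#'   (`sigma` entry), shrinking data-sparse years toward the overall
#'   detection level; `structure = "independent"` uses flat independent
#'   normals and `structure = "random_walk"` couples adjacent years with a
#'   fixed increment sd `rw_sd`.
#' @param beta prior on the list-length offsets.
#' @param sigma_u,sigma_rw priors on the site-effect and random-walk
#'   standard deviations: `list(dist = "uniform", max)` or
#'   `list(dist = "halfnormal", sd)`.
#' @return list of class `occ_priors`.
#' @export
occ_priors <- function(b0 = list(dist = "normal", mean = 0, sd = 10),
                       a = list(dist = "normal", mean = 0, sd = 10,
                                structure = "hierarchical",
                                sigma = list(dist = "uniform", max = 5)),
                       beta = list(dist = "normal", mean = 0, sd = 10),
                       sigma_u = list(dist = "uniform", max = 5),
                       sigma_rw = list(dist = "uniform", max = 5)) {
  structure(list(b0 = b0, a = a, beta = beta,
                 sigma_u = sigma_u, sigma_rw = sigma_rw),
            class = "occ_priors")
}

lp_sd_prior <- function(sigma, cfg) {
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  if (cfg$dist == "uniform") {
    if (sigma > cfg$max) -Inf else -log(cfg$max)
  } else if (cfg$dist == "halfnormal") {
    log(2) + stats::dnorm(sigma, 0, cfg$sd, log = TRUE)
  } else stop("unknown sd prior: ", cfg$dist)
}

lp_b0_prior <- function(b0, cfg) {
  if (cfg$dist == "normal") {
    sum(stats::dnorm(b0, cfg$mean, cfg$sd, log = TRUE))
  } else if (cfg$dist == "logistic") {
    sum(stats::dlogis(b0, 0, 1, log = TRUE))
  } else stop("unknown b0 prior: ", cfg$dist)
}

lp_prior_all <- function(params, priors, data) {
  b <- params$b
  lp <- lp_b0_prior(b[, 1L], priors$b0)
  if (data$n_years > 1L) {
    inc <- b[, -1L, drop = FALSE] - b[, -data$n_years, drop = FALSE]
    lp <- lp + sum(stats::dnorm(inc, 0, params$sigma_rw, log = TRUE))
  }
  lp <- lp + sum(stats::dnorm(params$u, 0, params$sigma_u, log = TRUE))
  if (identical(priors$a$structure, "random_walk")) {
    lp <- lp + stats::dnorm(params$a[1L], priors$a$mean, priors$a$sd,
                            log = TRUE)
    if (data$n_years > 1L) {
      lp <- lp + sum(stats::dnorm(diff(params$a), 0, priors$a$rw_sd,
                                  log = TRUE))
    }
  } else if (identical(priors$a$structure, "hierarchical")) {
    if (is.null(params$mu_a) || is.null(params$sigma_a)) {
      stop("hierarchical detection prior needs mu_a and sigma_a in params")
    }
    lp <- lp + sum(stats::dnorm(params$a, params$mu_a, params$sigma_a,
                                log = TRUE)) +
      stats::dnorm(params$mu_a, priors$a$mean, priors$a$sd, log = TRUE) +
      lp_sd_prior(params$sigma_a, priors$a$sigma)
  } else {
    lp <- lp + sum(stats::dnorm(params$a, priors$a$mean, priors$a$sd,
                                log = TRUE))
  }
  lp <- lp + stats::dnorm(params$beta1, priors$beta$mean, priors$beta$sd,
                          log = TRUE) +
    stats::dnorm(params$beta2, priors$beta$mean, priors$beta$sd, log = TRUE)
  lp + lp_sd_prior(params$sigma_u, priors$sigma_u) +
    lp_sd_prior(params$sigma_rw, priors$sigma_rw)
}

visit_logit_p <- function(params, data) {
  params$a[data$visit_year] +
    params$beta1 * (data$visit_dt == 2L) +
    params$beta2 * (data$visit_dt == 3L)
}

#' Log posterior kernel (augmented or z-marginalised)
#'
#' Returns the unnormalised log posterior density. The augmented form
#' includes the latent occupancy matrix `params$z`; the marginalised form
#' sums z out exactly per site-year (for site-years with at least one
#' detection, z = 1 is forced; for all-zero site-years the two-term mixture
#' `psi * prod(1-p) + (1-psi)` applies). Both forms share the same priors, so
#' summing the augmented kernel over all z configurations reproduces the
#' marginalised kernel exactly.
#'
#' @param params list with `b` (regions x years), `u`, `a`, `beta1`, `beta2`,
#'   `sigma_u`, `sigma_rw` and, for the augmented form, the binary matrix
#'   `z` (sites x years).
#' @param data an `occ_data` object.
#' @param priors an [occ_priors()] configuration.
#' @param form `"marginalized"` or `"augmented"`.
#' @return log density (`-Inf` for parameters outside the support or a z
#'   state contradicting a detection).
#' @export
log_posterior_kernel <- function(params, data, priors = occ_priors(),
                                 form = c("marginalized", "augmented")) {
  form <- match.arg(form)
  flat <- c(params$b, params$u, params$a, params$beta1, params$beta2,
            params$sigma_u, params$sigma_rw, params$mu_a, params$sigma_a)
  if (any(!is.finite(flat))) return(-Inf)

  lp <- lp_prior_all(params, priors, data)
  if (!is.finite(lp)) return(-Inf)

  eta <- state_logit(params, data)
  eta_p <- visit_logit_p(params, data)
  ll_v <- data$y * eta_p - log1pexp(eta_p)        # Bernoulli loglik per visit
  if (form == "augmented") {
    z <- params$z
    if (is.null(z) || !all(z %in% c(0, 1))) stop("augmented form needs binary z")
    zk <- z[data$k]
    if (any(data$y == 1L & zk == 0)) return(-Inf)  # detection forces z = 1
    lp <- lp + sum(z * eta - log1pexp(eta))
    lp <- lp + sum(ll_v[zk == 1])
    return(lp)
  }
  # marginalised over z, per site-year
  S1 <- rowsum(ll_v, data$k)                       # loglik sums by site-year
  uk <- as.integer(rownames(S1))
  psi_k <- stats::plogis(eta[uk])
  has_det <- data$det_vec[uk] > 0
  lp <- lp + sum(log(psi_k[has_det]) + S1[has_det])
  q <- exp(S1[!has_det])                           # all y = 0: S1 = log prod(1-p)
  lp <- lp + sum(log(psi_k[!has_det] * q + (1 - psi_k[!has_det])))
  lp
}

resolve_fixed <- function(fixed, data) {
  out <- fixed
  if (!is.null(out$u) && length(out$u) == 1L) {
    out$u <- rep(out$u, data$n_sites)
  }
  if (!is.null(out$a) && length(out$a) == 1L) {
    out$a <- rep(out$a, data$n_years)
  }
  if (!is.null(out$b) && length(out$b) == 1L) {
    out$b <- matrix(out$b, data$n_regions, data$n_years)
  }
  out
}

#' Draw from the posterior of the occupancy-detection model
#'
#' A Metropolis-within-Gibbs sampler: the latent occupancy states z are drawn
#' from their exact Bernoulli full conditionals; year effects b (within
#' even/odd year blocks, which are conditionally independent under the
#' random-walk prior), site effects u and detection year effects a are
#' updated with element-wise random-walk Metropolis steps; the list-length
#' offsets and the two standard deviations (on the log scale) with scalar
#' steps. Proposal scales adapt toward a 44% acceptance rate during burn-in
#' and are frozen afterwards. Draws are bit-reproducible for a fixed seed,
#' configuration and input.
#'
#' @param data an `occ_data` object.
#' @param chains number of independent chains (seeded `seed`, `seed+1`, ...).
#' @param iterations total iterations per chain.
#' @param burnin discarded initial iterations (`< iterations`).
#' @param thin keep every `thin`-th post-burn-in iteration; the retained
#'   draw count is `chains * floor((iterations - burnin) / thin)`.
#' @param seed integer seed.
#' @param priors an [occ_priors()] configuration.
#' @param fixed named list of parameters to hold fixed (any of `b`, `u`,
#'   `a`, `beta1`, `beta2`, `sigma_u`, `sigma_rw`; scalars are recycled).
#'   Fixed parameters receive no updates.
#' @param monitor_u keep per-site effect draws (memory scales with sites).
#' @return object of class `occ_draws`: arrays `b` (draws x regions x
#'   years), `a`, `beta`, `sigma_u`, `sigma_rw`, optionally `u`, the derived
#'   regional occupancy `occ` (draws x regions x years; per draw the mean of
#'   z over the modelled sites of each region), and a `chain` id per draw.
#' @export
sample_posterior <- function(data, chains = 3, iterations = 32000,
                             burnin = 30000, thin = 6, seed = 1,
                             priors = occ_priors(), fixed = list(),
                             monitor_u = FALSE) {
  stopifnot(inherits(data, "occ_data"), chains >= 1, burnin < iterations,
            thin >= 1)
  fixed <- resolve_fixed(fixed, data)
  S_chain <- floor((iterations - burnin) / thin)
  if (S_chain < 1) stop("no retained draws: increase iterations or lower thin")
  S <- chains * S_chain
  R <- data$n_regions; Tn <- data$n_years; n <- data$n_sites

  out <- list(
    b = array(NA_real_, c(S, R, Tn)),
    a = matrix(NA_real_, S, Tn),
    beta = matrix(NA_real_, S, 2,
                  dimnames = list(NULL, c("beta1", "beta2"))),
    sigma_u = numeric(S), sigma_rw = numeric(S),
    mu_a = numeric(S), sigma_a = numeric(S),
    occ = array(NA_real_, c(S, R, Tn)),
    chain = rep(seq_len(chains), each = S_chain))
  if (monitor_u) out$u <- matrix(NA_real_, S, n)

  n_region <- tabulate(data$region, R)
  forced <- data$det_vec > 0                      # site-years with a detection
  uk_all <- sort(unique(data$k))
  uk0 <- uk_all[data$det_vec[uk_all] == 0]        # visited, zero detections
  novisit <- which(data$nvis_vec == 0)
  vis0 <- which(data$det_vec[data$k] == 0)        # visits at zero-det cells
  g0 <- make_grouper(data$k[vis0])                # labels == uk0 (sorted)
  gy <- make_grouper(data$visit_year)             # visits grouped by year
  is_short <- as.numeric(data$visit_dt == 2L)
  is_long <- as.numeric(data$visit_dt == 3L)
  even_t <- if (Tn >= 2L) seq(2L, Tn, by = 2L) else integer(0)
  odd_t <- seq(1L, Tn, by = 2L)
  region_onehot <- outer(seq_len(R), data$region,
                         function(r, g) as.numeric(g == r))  # R x n_sites

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    st <- init_state(data, priors, fixed)
    prop <- list(b = 0.4, u = 0.6, a = 0.4, beta = 0.3,
                 ls_u = 0.5, ls_rw = 0.5, ls_a = 0.5)
    acc <- stats::setNames(numeric(length(prop)), names(prop))
    att <- acc
    free <- stats::setNames(!(c("b", "u", "a", "beta1", "beta2",
                                "sigma_u", "sigma_rw") %in% names(fixed)),
                            c("b", "u", "a", "beta1", "beta2",
                              "sigma_u", "sigma_rw"))
    kept <- 0L
    ## cached linear predictors (updated incrementally on acceptance)
    eta <- st$b[data$region, , drop = FALSE] + st$u
    Leta <- log1pexp(eta)
    eta_p <- st$a[data$visit_year] + st$beta1 * is_short +
      st$beta2 * is_long
    Lp <- log1pexp(eta_p)
    for (it in seq_len(iterations)) {
      ## --- latent z (exact conditional) --------------------------------
      psi <- stats::plogis(eta)
      z <- st$z
      z[forced] <- 1
      if (length(uk0) > 0L) {
        lq0 <- group_sums(-Lp[vis0], g0)          # log prod(1-p) by cell
        psi0 <- psi[uk0]
        pz <- psi0 * exp(lq0)
        pz <- pz / (pz + 1 - psi0)
        z[uk0] <- stats::rbinom(length(uk0), 1L, pz)
      }
      if (length(novisit) > 0L) {
        z[novisit] <- stats::rbinom(length(novisit), 1L, psi[novisit])
      }
      st$z <- z

      ## --- state year effects b, even/odd year blocks ------------------
      if (free[["b"]]) {
        for (block in list(odd_t, even_t)) {
          if (length(block) == 0L) next
          db <- matrix(stats::rnorm(R * length(block), 0, prop$b), R)
          bp <- st$b[, block, drop = FALSE] + db
          eta_cur <- eta[, block, drop = FALSE]
          eta_new <- eta_cur + db[data$region, , drop = FALSE]
          Lnew <- log1pexp(eta_new)
          dll <- z[, block, drop = FALSE] * (eta_new - eta_cur) -
            Lnew + Leta[, block, drop = FALSE]
          dreg <- region_onehot %*% dll             # R x |block|
          dpri <- rw_prior_delta(st$b, bp, block, st$sigma_rw, priors$b0)
          ok <- log(stats::runif(R * length(block))) < (dreg + dpri)
          if (any(ok)) {
            st$b[, block][ok] <- bp[ok]
            okm <- ok[data$region, , drop = FALSE]  # expand to sites
            eta[, block][okm] <- eta_new[okm]
            Leta[, block][okm] <- Lnew[okm]
          }
          acc[["b"]] <- acc[["b"]] + sum(ok); att[["b"]] <- att[["b"]] +
            length(ok)
        }
      }

      ## --- site effects u (element-wise) -------------------------------
      if (free[["u"]]) {
        du <- stats::rnorm(n, 0, prop$u)
        up <- st$u + du
        eta_new <- eta + du
        Lnew <- log1pexp(eta_new)
        dll <- rowSums(z * (eta_new - eta) - Lnew + Leta)
        dpri <- stats::dnorm(up, 0, st$sigma_u, log = TRUE) -
          stats::dnorm(st$u, 0, st$sigma_u, log = TRUE)
        ok <- log(stats::runif(n)) < (dll + dpri)
        if (any(ok)) {
          st$u[ok] <- up[ok]
          eta[ok, ] <- eta_new[ok, , drop = FALSE]
          Leta[ok, ] <- Lnew[ok, , drop = FALSE]
        }
        acc[["u"]] <- acc[["u"]] + sum(ok); att[["u"]] <- att[["u"]] + n
      }

      ## --- detection year effects a ------------------------------------
      zk <- z[data$k]
      if (free[["a"]]) {
        da <- stats::rnorm(Tn, 0, prop$a)
        ap <- st$a + da
        ep_new <- eta_p + da[data$visit_year]
        Lp_new <- log1pexp(ep_new)
        dv <- zk * (data$y * (ep_new - eta_p) - Lp_new + Lp)
        dt_year <- numeric(Tn)
        dt_year[gy$labels] <- group_sums(dv, gy)
        if (identical(priors$a$structure, "random_walk")) {
          # joint accept for the coupled random-walk trajectory
          dpri <- a_rw_prior_delta(st$a, ap, st, priors)
          if (log(stats::runif(1)) < sum(dt_year) + dpri) {
            st$a <- ap
            eta_p <- ep_new
            Lp <- Lp_new
            acc[["a"]] <- acc[["a"]] + Tn
          }
          att[["a"]] <- att[["a"]] + Tn
        } else {
          if (identical(priors$a$structure, "hierarchical")) {
            dpri <- stats::dnorm(ap, st$mu_a, st$sigma_a, log = TRUE) -
              stats::dnorm(st$a, st$mu_a, st$sigma_a, log = TRUE)
          } else {
            dpri <- stats::dnorm(ap, priors$a$mean, priors$a$sd,
                                 log = TRUE) -
              stats::dnorm(st$a, priors$a$mean, priors$a$sd, log = TRUE)
          }
          ok <- log(stats::runif(Tn)) < (dt_year + dpri)
          if (any(ok)) {
            st$a[ok] <- ap[ok]
            okv <- ok[data$visit_year]
            eta_p[okv] <- ep_new[okv]
            Lp[okv] <- Lp_new[okv]
          }
          acc[["a"]] <- acc[["a"]] + sum(ok); att[["a"]] <- att[["a"]] + Tn
        }
        if (identical(priors$a$structure, "hierarchical")) {
          # mu_a: conjugate normal update given a and sigma_a
          prec <- Tn / st$sigma_a^2 + 1 / priors$a$sd^2
          mean_post <- (sum(st$a) / st$sigma_a^2 +
                          priors$a$mean / priors$a$sd^2) / prec
          st$mu_a <- stats::rnorm(1, mean_post, sqrt(1 / prec))
          # sigma_a: log-scale random-walk Metropolis
          snew <- st$sigma_a * exp(stats::rnorm(1, 0, prop$ls_a))
          dsa <- sum(stats::dnorm(st$a, st$mu_a, snew, log = TRUE)) -
            sum(stats::dnorm(st$a, st$mu_a, st$sigma_a, log = TRUE)) +
            lp_sd_prior(snew, priors$a$sigma) -
            lp_sd_prior(st$sigma_a, priors$a$sigma) +
            log(snew) - log(st$sigma_a)
          if (is.finite(dsa) && log(stats::runif(1)) < dsa) {
            st$sigma_a <- snew
            acc[["ls_a"]] <- acc[["ls_a"]] + 1
          }
          att[["ls_a"]] <- att[["ls_a"]] + 1
        }
      }

      ## --- list-length offsets -----------------------------------------
      for (j in 1:2) {
        nm <- paste0("beta", j)
        if (!free[[nm]]) next
        cur <- st[[nm]]
        new <- cur + stats::rnorm(1, 0, prop$beta)
        seldt <- if (j == 1L) is_short else is_long
        sel <- which(seldt == 1)
        d <- new - cur
        ep_new <- eta_p[sel] + d
        Lp_new <- log1pexp(ep_new)
        zsel <- zk[sel]
        dll <- sum(zsel * (data$y[sel] * d - Lp_new + Lp[sel]))
        dpri <- stats::dnorm(new, priors$beta$mean, priors$beta$sd,
                             log = TRUE) -
          stats::dnorm(cur, priors$beta$mean, priors$beta$sd, log = TRUE)
        if (log(stats::runif(1)) < dll + dpri) {
          st[[nm]] <- new
          eta_p[sel] <- ep_new
          Lp[sel] <- Lp_new
          acc[["beta"]] <- acc[["beta"]] + 1
        }
        att[["beta"]] <- att[["beta"]] + 1
      }

      ## --- standard deviations (log-scale random walk) -----------------
      if (free[["sigma_u"]]) {
        snew <- st$sigma_u * exp(stats::rnorm(1, 0, prop$ls_u))
        d <- sum(stats::dnorm(st$u, 0, snew, log = TRUE)) -
          sum(stats::dnorm(st$u, 0, st$sigma_u, log = TRUE)) +
          lp_sd_prior(snew, priors$sigma_u) -
          lp_sd_prior(st$sigma_u, priors$sigma_u) +
          log(snew) - log(st$sigma_u)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          st$sigma_u <- snew
          acc[["ls_u"]] <- acc[["ls_u"]] + 1
        }
        att[["ls_u"]] <- att[["ls_u"]] + 1
      }
      if (free[["sigma_rw"]] && Tn > 1L) {
        inc <- st$b[, -1L, drop = FALSE] - st$b[, -Tn, drop = FALSE]
        snew <- st$sigma_rw * exp(stats::rnorm(1, 0, prop$ls_rw))
        d <- sum(stats::dnorm(inc, 0, snew, log = TRUE)) -
          sum(stats::dnorm(inc, 0, st$sigma_rw, log = TRUE)) +
          lp_sd_prior(snew, priors$sigma_rw) -
          lp_sd_prior(st$sigma_rw, priors$sigma_rw) +
          log(snew) - log(st$sigma_rw)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          st$sigma_rw <- snew
          acc[["ls_rw"]] <- acc[["ls_rw"]] + 1
        }
        att[["ls_rw"]] <- att[["ls_rw"]] + 1
      }

      ## --- adapt during burn-in ----------------------------------------
      if (it <= burnin && it %% 50L == 0L) {
        for (nm in names(prop)) {
          if (att[[nm]] > 0) {
            rate <- acc[[nm]] / att[[nm]]
            prop[[nm]] <- min(5, max(0.01,
                                     prop[[nm]] * exp(0.7 * (rate - 0.44))))
          }
        }
        acc[] <- 0; att[] <- 0
      }

      ## --- store -------------------------------------------------------
      if (it > burnin && (it - burnin) %% thin == 0L && kept < S_chain) {
        kept <- kept + 1L
        s <- (ch - 1L) * S_chain + kept
        out$b[s, , ] <- st$b
        out$a[s, ] <- st$a
        out$beta[s, ] <- c(st$beta1, st$beta2)
        out$sigma_u[s] <- st$sigma_u
        out$sigma_rw[s] <- st$sigma_rw
        out$mu_a[s] <- st$mu_a
        out$sigma_a[s] <- st$sigma_a
        out$occ[s, , ] <- (region_onehot %*% st$z) / n_region
        if (monitor_u) out$u[s, ] <- st$u
      }
    }
  }

  out$region_levels <- data$region_levels
  out$n_sites_region <- stats::setNames(n_region, data$region_levels)
  out$n_years <- Tn
  out$config <- list(chains = chains, iterations = iterations,
                     burnin = burnin, thin = thin, seed = seed)
  class(out) <- "occ_draws"
  out
}

init_state <- function(data, priors, fixed) {
  R <- data$n_regions; Tn <- data$n_years; n <- data$n_sites
  naive <- vapply(seq_len(R), function(r) {
    cells <- data$det_vec[rep(data$region == r, Tn) &
                            data$nvis_vec > 0]
    if (length(cells) == 0L) 0.5 else mean(cells > 0)
  }, numeric(1))
  naive_det <- mean(data$y)
  for (try in 1:10) {
    st <- list(
      b = matrix(stats::qlogis(pmin(pmax(naive, 0.05), 0.95)), R, Tn) +
        matrix(stats::rnorm(R * Tn, 0, 0.1), R, Tn),
      u = stats::rnorm(n, 0, 0.1),
      a = rep(stats::qlogis(pmin(pmax(naive_det, 0.05), 0.95)), Tn) +
        stats::rnorm(Tn, 0, 0.1),
      beta1 = 0, beta2 = 0, sigma_u = 1, sigma_rw = 0.5,
      mu_a = stats::qlogis(pmin(pmax(naive_det, 0.05), 0.95)),
      sigma_a = 0.5)
    st[names(fixed)] <- fixed
    z <- matrix(0L, n, Tn)
    z[data$det_vec > 0] <- 1L
    free_cells <- data$det_vec == 0
    z[free_cells] <- stats::rbinom(sum(free_cells), 1L, 0.3)
    st$z <- z
    lp <- log_posterior_kernel(st, data, priors, form = "augmented")
    if (is.finite(lp)) return(st)
  }
  stop("could not find a finite starting state after 10 attempts; ",
       "check priors and fixed parameters")
}

rw_prior_delta <- function(b, bp, block, sigma_rw, b0_prior) {
  # prior log-density change for proposals bp in year columns `block`,
  # neighbours held at current values (valid within an even/odd block)
  R <- nrow(b); Tn <- ncol(b)
  d <- matrix(0, R, length(block))
  for (j in seq_along(block)) {
    t <- block[j]
    cur <- b[, t]; new <- bp[, j]
    if (t == 1L) {
      d[, j] <- d[, j] + vapply(seq_len(R), function(r)
        lp_b0_prior(new[r], b0_prior) - lp_b0_prior(cur[r], b0_prior),
        numeric(1))
    } else {
      d[, j] <- d[, j] +
        stats::dnorm(new, b[, t - 1L], sigma_rw, log = TRUE) -
        stats::dnorm(cur, b[, t - 1L], sigma_rw, log = TRUE)
    }
    if (t < Tn) {
      d[, j] <- d[, j] +
        stats::dnorm(b[, t + 1L], new, sigma_rw, log = TRUE) -
        stats::dnorm(b[, t + 1L], cur, sigma_rw, log = TRUE)
    }
  }
  d
}

a_rw_prior_delta <- function(a, ap, st, priors) {
  lp <- function(x) {
    v <- stats::dnorm(x[1L], priors$a$mean, priors$a$sd, log = TRUE)
    if (length(x) > 1L) {
      v <- v + sum(stats::dnorm(diff(x), 0, priors$a$rw_sd, log = TRUE))
    }
    v
  }
  lp(ap) - lp(a)
}

#' @export
print.occ_draws <- function(x, ...) {
  cat("posterior draws:", length(x$chain), "retained (",
      x$config$chains, "chains x",
      floor((x$config$iterations - x$config$burnin) / x$config$thin),
      ")\n")
  cat("regions:", paste(x$region_levels, collapse = ", "),
      "| years:", x$n_years, "\n")
  invisible(x)
}

#' Split-chain Gelman-Rubin statistic
#'
#' Computes the potential scale reduction factor on split chains: each chain
#' is halved, the between- and within-chain variances of the resulting
#' 2m sequences are compared, and
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate that the
#' chains are mixing over the same distribution.
#'
#' @param draws numeric matrix, one column per chain (>= 2 draws each), or a
#'   vector accompanied by `chain`.
#' @param chain optional chain index per draw when `draws` is a vector.
#' @return Rhat, or `NA` (with a warning) when all chains are degenerate
#'   (zero within-chain variance).
#' @export
gelman_rubin <- function(draws, chain = NULL) {
  if (!is.null(chain)) {
    draws <- do.call(cbind, split(draws, chain))
  }
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2L || n < 4L) stop("need >= 2 chains of >= 4 draws for split Rhat")
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[half + seq_len(half), , drop = FALSE])
  W <- mean(apply(sub, 2, stats::var))
  if (!is.finite(W) || W <= .Machine$double.eps * max(1, mean(sub)^2)) {
    warning("zero within-chain variance: Rhat undefined")
    return(NA_real_)
  }
  B <- half * stats::var(colMeans(sub))
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence report for a fitted species
#'
#' Computes the split-chain Rhat of the first- and last-year regional
#' occupancy (the quantities species trends rest on) plus the detection
#' offsets and variance parameters.
#'
#' @param draws an `occ_draws` object.
#' @param threshold Rhat above which a quantity is flagged (default 1.1).
#' @return data.frame `quantity`, `rhat`, `converged`; attribute
#'   `"converged"` is `TRUE` when every first/last-year occupancy Rhat is
#'   below `threshold` (degenerate-but-agreeing chains count as converged).
#' @export
convergence_report <- function(draws, threshold = 1.1) {
  Tn <- draws$n_years
  qs <- list()
  for (r in seq_along(draws$region_levels)) {
    for (t in c(1L, Tn)) {
      nm <- sprintf("occ[%s,%s]", draws$region_levels[r],
                    if (t == 1L) "first" else "last")
      qs[[nm]] <- draws$occ[, r, t]
    }
  }
  qs[["beta1"]] <- draws$beta[, 1L]
  qs[["beta2"]] <- draws$beta[, 2L]
  qs[["sigma_u"]] <- draws$sigma_u
  qs[["sigma_rw"]] <- draws$sigma_rw
  rh <- vapply(qs, function(x) {
    tryCatch(suppressWarnings(gelman_rubin(x, chain = draws$chain)),
             error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(quantity = names(qs), rhat = unname(rh),
                    converged = is.na(rh) | rh < threshold)
  occ_rows <- grepl("^occ\\[", out$quantity)
  # a constant-z quantity (rhat NA) is treated as agreeing chains only if
  # the chain means coincide; otherwise it stays flagged
  for (i in which(occ_rows & is.na(out$rhat))) {
    mns <- tapply(qs[[out$quantity[i]]], draws$chain, mean)
    out$converged[i] <- max(mns) - min(mns) < 1e-12
  }
  attr(out, "converged") <- all(out$converged[occ_rows])
  out
}

#' Filter species on first/last-year occupancy convergence
#'
#' Species whose first- and last-year occupancy estimates both have
#' Rhat below the threshold are retained; species with a missing Rhat are
#' flagged and excluded rather than silently retained.
#'
#' @param reports data.frame with columns `species`, `rhat_first`,
#'   `rhat_last`.
#' @param threshold Rhat threshold (default 1.1).
#' @return data.frame `species`, `retained`, `flagged` (`TRUE` when an Rhat
#'   was missing).
#' @export
convergence_filter <- function(reports, threshold = 1.1) {
  stopifnot(all(c("species", "rhat_first", "rhat_last") %in% names(reports)))
  flagged <- is.na(reports$rhat_first) | is.na(reports$rhat_last)
  retained <- !flagged & reports$rhat_first < threshold &
    reports$rhat_last < threshold
  if (any(flagged)) {
    message(sum(flagged), " species flagged for missing Rhat values")
  }
  data.frame(species = reports$species, retained = retained,
             flagged = flagged)
}
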