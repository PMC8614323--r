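#' Sex-specific growth curves of the synthetic herd
#'
#' Saturating (monotone) growth curves mapping age in years to expected body
#' weight in kg, parameterized to approximate the published herd summaries
#' (females: mean 85.7 kg; males: light calves/yearlings growing into heavy
#' stags).
#'
#' @param age numeric age in years.
#' @return expected body weight (kg).
#' @keywords internal
growth_curve <- function(age, sex) {
  ifelse(sex == "m",
         160 * (1 - exp(-0.32 * (age + 0.6))),
         106 * (1 - 0.42 * exp(-0.35 * age)))
}

center <- function(z) z - mean(z)

# standardized right-skewed quantile sample: a permuted, exactly
# standardized quantile grid of a shifted gamma (mean 0, SD 1, support
# bounded below near -sqrt(k); small k = strong skew, most values near the
# lower bound with a long right tail of heavily bitten outliers). Drawing
# quantiles rather than iid values conditions the generator on the realized
# effect distribution: the sample SD of every random component equals its
# configured value exactly, whatever the skew. `k = NULL` gives a Gaussian
# grid. Only the permutation consumes random numbers.
qdraw <- function(n, k = NULL) {
  if (n == 1L) return(0)
  u <- (seq_len(n) - 0.5) / n
  z <- if (is.null(k) || !is.finite(k) || k <= 0) {
    stats::qnorm(u)
  } else {
    (stats::qgamma(u, shape = k) - k) / sqrt(k)
  }
  z <- (z - mean(z)) / stats::sd(z)
  sample(z)
}

draw_ages <- function(n, sex) {
  if (n == 0L) return(numeric(0))
  if (sex == "f") {
    # quarter of the hinds are yearlings; the rest right-skewed adults
    young <- stats::runif(n, 1, 1.2)
    adult <- 1 + stats::rgamma(n, shape = 1.6, scale = 3.2)
    age <- ifelse(stats::runif(n) < 0.28, young, adult)
    pmin(pmax(age, 1), 21)
  } else {
    # male herd mixes calves/yearlings with a broad spread of stags
    young <- stats::runif(n, 0.35, 1.2)
    adult <- 0.5 + stats::rgamma(n, shape = 1.3, scale = 2.8)
    age <- ifelse(stats::runif(n) < 0.5, young, adult)
    pmin(pmax(age, 0.3), 15)
  }
}

split_groups <- function(ids, n_groups, shuffle = TRUE) {
  n <- length(ids)
  if (shuffle) ids <- sample(ids)
  # uneven group sizes (the farm's groups differed substantially)
  w <- stats::rgamma(n_groups, shape = 3, rate = 1)
  sizes <- pmax(floor(w / sum(w) * n), 2L)
  while (sum(sizes) < n) sizes[which.max(w)] <- sizes[which.max(w)] + 1L
  while (sum(sizes) > n) {
    k <- which.max(sizes)
    sizes[k] <- sizes[k] - 1L
  }
  split(ids, rep(seq_len(n_groups), times = sizes))
}

#' Generate the synthetic herd roster
#'
#' Draws animals with sex, age, body weight (from the sex-specific growth
#' curve plus a persistent animal-level deviation), day-of-year of birth, a
#' latent dominance propensity correlated with the age/weight composite at
#' `cfg$rank_trait_correlation`, the year the animal enters the monitored
#' herd and how many years it stays, and an initial single-sex group
#' assignment.
#'
#' @param cfg a [generator_config()].
#' @return data frame (roster), one row per animal.
#' @export
generate_herd <- function(cfg) {
  validate_config(cfg)
  with_stream(cfg$seed, "herd", {
    n <- cfg$n_females + cfg$n_males
    sex <- rep(c("f", "m"), c(cfg$n_females, cfg$n_males))
    id <- sprintf("%s%04d", toupper(sex), c(seq_len(cfg$n_females),
                                            seq_len(cfg$n_males)))
    age <- c(draw_ages(cfg$n_females, "f"), draw_ages(cfg$n_males, "m"))
    weight_dev <- stats::rnorm(n, 0, 10)
    weight <- growth_curve(age, sex) + weight_dev
    dob <- round(pmin(pmax(stats::rnorm(n, 135, 18), 85), 195))

    z_age <- as.numeric(scale(age))
    z_w <- as.numeric(scale(weight))
    comp <- as.numeric(scale(0.6 * z_age + 0.4 * z_w))
    rho <- cfg$rank_trait_correlation
    latent_rank <- rho * comp + sqrt(1 - rho^2) * stats::rnorm(n)

    # early study years carried far more animals than late ones
    wy <- c(rep(1.6, min(6L, cfg$n_years)),
            rep(0.6, max(cfg$n_years - 6L, 0L)))
    entry_year <- cfg$start_year - 1L +
      sample(cfg$n_years, n, replace = TRUE, prob = wy)
    span <- sample(seq_along(cfg$mean_presence_weights), n, replace = TRUE,
                   prob = cfg$mean_presence_weights)

    roster <- data.frame(
      id = id, sex = sex, age_years = age, body_weight_kg = weight,
      weight_dev = weight_dev, date_of_birth_doy = dob,
      latent_rank = latent_rank, entry_year = entry_year, span = span,
      stringsAsFactors = FALSE
    )
    grp <- character(n)
    for (s in c("f", "m")) {
      groups <- split_groups(roster$id[roster$sex == s], cfg$n_groups_per_sex)
      for (g in seq_along(groups)) {
        grp[roster$id %in% groups[[g]]] <- sprintf("%sG%d", s, g)
      }
    }
    roster$group_id <- grp
    roster
  })
}

#' Generate daily July-August weather
#'
#' One record per July-August day per year: a within-season sinusoidal trend
#' plus Gaussian year-level shifts (so seasonal heat stress differs among
#' years) plus i.i.d. daily noise, truncated to physical ranges.
#'
#' @param cfg a [generator_config()].
#' @return data frame with columns `date`, `year`, `doy`, `T`, `Hr`, `W`,
#'   `SR`.
#' @export
generate_weather <- function(cfg) {
  stopifnot(cfg$n_years >= 1L)
  wp <- cfg$weather_params
  with_stream(cfg$seed, "weather", {
    out <- list()
    for (k in seq_len(cfg$n_years)) {
      year <- cfg$start_year + k - 1L
      dates <- seq(as.Date(sprintf("%d-07-01", year)),
                   as.Date(sprintf("%d-08-31", year)), by = "day")
      nd <- length(dates)
      idx <- seq_len(nd)
      season <- sin(pi * idx / nd) # peaks mid window
      shift <- vapply(wp, function(p) stats::rnorm(1, 0, p$year_sd), 0)
      tt <- wp$T$mean + shift[["T"]] + (wp$T$amp %||% 0) * season +
        stats::rnorm(nd, 0, wp$T$day_sd)
      hr <- pmin(pmax(wp$Hr$mean + shift[["Hr"]] +
                        stats::rnorm(nd, 0, wp$Hr$day_sd), 5), 100)
      w <- pmax(wp$W$mean + shift[["W"]] + stats::rnorm(nd, 0, wp$W$day_sd),
                0.1)
      sr <- pmax(wp$SR$mean + shift[["SR"]] + (wp$SR$amp %||% 0) * season +
                   stats::rnorm(nd, 0, wp$SR$day_sd), 3)
      out[[k]] <- data.frame(
        date = dates, year = year, doy = as.integer(format(dates, "%j")),
        T = tt, Hr = hr, W = w, SR = sr
      )
    }
    do.call(rbind, out)
  })
}

interaction_behaviours <- c(
  "head butting" = 0.18, "boxing" = 0.08, "pelt biting" = 0.22,
  "kicking" = 0.08, "pushing" = 0.12, "chasing" = 0.10,
  "walking/running away" = 0.08, "spatial displacement" = 0.08,
  "visual threat" = 0.06
)

#' Simulate agonistic interaction records
#'
#' For every within-group dyad the number of recorded interactions is
#' Poisson with mean `cfg$interactions_per_dyad`; in each interaction the
#' animal with the higher latent dominance propensity is the aggressor with
#' probability `plogis(steepness * rank difference)` (a Bradley-Terry-style
#' outcome model that reduces to a fair coin at equal rank). Behaviour types
#' are drawn from the observed repertoire.
#'
#' @param roster data frame with columns `id`, `group_id`, `latent_rank`.
#' @param cfg a [generator_config()].
#' @param year calendar year used for the record dates.
#' @param stream RNG substream name.
#' @return data frame of interaction records (`date`, `aggressor_id`,
#'   `aggrieved_id`, `behaviour`, `group_id`).
#' @export
simulate_interactions <- function(roster, cfg, year = cfg$start_year,
                                  stream = "interactions") {
  stopifnot(cfg$interaction_steepness > 0)
  with_stream(cfg$seed, paste0(stream, "_", year), {
    res <- list()
    window <- as.integer(as.Date(sprintf("%d-10-31", year)) -
                           as.Date(sprintf("%d-04-01", year)))
    for (g in unique(roster$group_id)) {
      members <- roster[roster$group_id == g, ]
      if (nrow(members) < 2L) {
        warning("group ", g, " has fewer than 2 animals; no interactions")
        next
      }
      dy <- utils::combn(nrow(members), 2L)
      counts <- stats::rpois(ncol(dy), cfg$interactions_per_dyad)
      i <- rep(dy[1, ], counts)
      j <- rep(dy[2, ], counts)
      if (!length(i)) next
      dr <- members$latent_rank[i] - members$latent_rank[j]
      p_i_wins <- stats::plogis(cfg$interaction_steepness * dr)
      i_wins <- stats::runif(length(i)) < p_i_wins
      res[[g]] <- data.frame(
        date = as.Date(sprintf("%d-04-01", year)) +
          sample.int(window, length(i), replace = TRUE) - 1L,
        aggressor_id = members$id[ifelse(i_wins, i, j)],
        aggrieved_id = members$id[ifelse(i_wins, j, i)],
        behaviour = sample(names(interaction_behaviours), length(i),
                           replace = TRUE, prob = interaction_behaviours),
        group_id = g,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, res)
    if (is.null(out)) {
      out <- data.frame(date = as.Date(character(0)),
                        aggressor_id = character(0),
                        aggrieved_id = character(0),
                        behaviour = character(0), group_id = character(0))
    }
    rownames(out) <- NULL
    out
  })
}

#' Observed-scale calibration of a censored latent response
#'
#' The ordinal pelt class is a censored (floor at class 1, ceiling at 5),
#' discretized observation of a continuous latent scale. Censoring shrinks
#' every location parameter of a linear model fitted to the observed
#' classes — each fixed-effect coefficient and each random-effect SD by its
#' own factor. The configured coefficients describe the *observed-scale*
#' model (that is the scale on which such coefficients are estimated in
#' practice), so the generator derives latent-scale parameters by inverting
#' the censoring map: on an auxiliary replicate of the random draws (its own
#' RNG substream, so the delivered panel keeps genuine sampling noise) it
#' iterates
#' \enumerate{
#'   \item discretize the current latent model the way the panel will be,
#'   \item re-estimate the fixed effects by exact GLS with the known
#'     variance ratios (a Henderson/Woodbury solve over the crossed
#'     factors, matching what an REML fit recovers) and measure each
#'     random component's transmitted variance by an ANOVA
#'     method-of-moments estimator,
#'   \item move each latent coefficient and component scale so the
#'     recovered values approach their targets (damped steps, bounded
#'     scales).
#' }
#' The returned map is deterministic given `(seed, stream)`.
#'
#' @param X design matrix *without* intercept (the fixed-effect columns of
#'   the model, observed scale).
#' @param beta named target coefficient vector including `"(Intercept)"`;
#'   names must match `colnames(X)` plus the intercept.
#' @param groups list of integer index vectors (one per random-intercept
#'   factor) mapping each row of `X` to a factor level.
#' @param sd_target numeric vector of target random-effect SDs (same order
#'   as `groups`).
#' @param resid_target target residual SD.
#' @param seed,stream RNG substream of the auxiliary draws.
#' @param n_rep auxiliary replicates stacked to stabilise the map.
#' @param lower,upper censoring bounds of the class scale.
#' @param skew_k gamma shape of the standardized component draws (`NULL`
#'   for Gaussian).
#' @param snap logical: discretize to the 0.25 class grid (weekly panels)
#'   or only clamp (continuous seasonal-mean responses).
#' @param max_iter,tol iteration control.
#' @return list with `beta_lat` (latent coefficients), `mu0` (latent
#'   intercept), `s` (latent scales of the random components and, last, the
#'   residual), and `kappa` (final uncensored fraction).
#' @export
censoring_calibration <- function(X, beta, groups, sd_target, resid_target,
                                  seed, stream, n_rep = 24L,
                                  lower = 1, upper = 5, skew_k = NULL,
                                  snap = TRUE, max_iter = 30L, tol = 2e-4) {
  stopifnot(setequal(names(beta), c("(Intercept)", colnames(X))))
  n <- nrow(X)
  b0_t <- beta[["(Intercept)"]]
  bt <- beta[colnames(X)]
  target <- c(b0_t, bt)
  nG <- length(groups)
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)

  # aggregates for the exact GLS solve (Henderson/Woodbury with known
  # variance ratios): indicator cross-products and group totals of X
  counts <- lapply(groups, tabulate)
  sizes <- vapply(counts, length, 0L)
  off <- c(0L, cumsum(sizes))
  ZX <- lapply(groups, function(g) rowsum(X1, g))
  cross <- list()
  for (g1 in seq_len(nG)) {
    for (g2 in seq_len(nG)) {
      if (g2 > g1) {
        cross[[paste(g1, g2)]] <-
          unclass(table(groups[[g1]], groups[[g2]]))
      }
    }
  }
  XtX <- crossprod(X1)
  qx <- qr(X1)

  gls_beta <- function(y_list, s) {
    se2 <- s[nG + 1]^2
    active <- which(s[seq_len(nG)] > 0)
    if (se2 <= 0 || length(active) == 0L) {
      # degenerate: plain OLS on the stacked replicates
      ob <- rowMeans(vapply(y_list, function(y) qr.coef(qx, y),
                            numeric(p)))
      return(ob)
    }
    nz <- sum(sizes[active])
    M <- diag(nz)
    W <- matrix(0, nz, p)
    pos <- c(0L, cumsum(sizes[active]))
    for (ii in seq_along(active)) {
      g <- active[ii]
      idx <- (pos[ii] + 1L):pos[ii + 1L]
      a <- s[g] / s[nG + 1]
      M[idx, idx] <- M[idx, idx] + diag(a^2 * counts[[g]],
                                        nrow = sizes[g])
      W[idx, ] <- a * ZX[[g]]
      if (ii < length(active)) {
        for (jj in (ii + 1L):length(active)) {
          h <- active[jj]
          jdx <- (pos[jj] + 1L):pos[jj + 1L]
          ab <- (s[g] / s[nG + 1]) * (s[h] / s[nG + 1])
          cr <- cross[[paste(g, h)]]
          M[idx, jdx] <- M[idx, jdx] + ab * cr
          M[jdx, idx] <- M[jdx, idx] + ab * t(cr)
        }
      }
    }
    MW <- solve(M, W)
    A <- XtX - crossprod(W, MW)
    bs <- vapply(y_list, function(y) {
      u <- numeric(nz)
      for (ii in seq_along(active)) {
        g <- active[ii]
        idx <- (pos[ii] + 1L):pos[ii + 1L]
        u[idx] <- (s[g] / s[nG + 1]) * rowsum(y, groups[[g]])
      }
      b <- crossprod(X1, y) - crossprod(MW, u)
      as.numeric(solve(A, b))
    }, numeric(p))
    rowMeans(bs)
  }

  if (resid_target == 0 && all(sd_target == 0)) {
    # degenerate noiseless configuration: nothing to calibrate
    return(list(beta_lat = bt, mu0 = b0_t,
                s = c(sd_target, resid_target),
                kappa = as.numeric(b0_t > lower && b0_t < upper)))
  }
  with_stream(seed, stream, {
    # auxiliary standardized draws, n_rep independent replicates
    zg <- lapply(seq_len(n_rep), function(r) {
      lapply(seq_len(nG), function(g) qdraw(sizes[g], skew_k)[groups[[g]]])
    })
    ze <- lapply(seq_len(n_rep), function(r) qdraw(n, skew_k))

    beta_lat <- bt
    mu0 <- b0_t
    s <- c(sd_target, resid_target)
    kappa <- 1
    for (it in seq_len(max_iter)) {
      fe <- mu0 + as.numeric(X %*% beta_lat)
      y_list <- vector("list", n_rep)
      kap <- 0
      for (r in seq_len(n_rep)) {
        L <- fe + ze[[r]] * s[nG + 1]
        for (g in seq_len(nG)) L <- L + zg[[r]][[g]] * s[g]
        kap <- kap + mean(L > lower & L < upper)
        y_list[[r]] <- if (snap) snap_class(L) else
          pmin(pmax(L, lower), upper)
      }
      kappa <- max(kap / n_rep, 0.05)
      ob <- gls_beta(y_list, s)
      step_b <- (target - ob) / max(kappa, 0.25)
      delta <- max(abs(step_b))
      mu0 <- mu0 + 0.6 * step_b[1]
      beta_lat <- beta_lat + 0.6 * step_b[-1]
      yy <- unlist(y_list, use.names = FALSE)
      slopes <- numeric(nG)
      for (g in seq_len(nG)) {
        if (sd_target[g] == 0) {
          s[g] <- 0
          next
        }
        zz <- unlist(lapply(zg, function(z) z[[g]]), use.names = FALSE)
        slopes[g] <- stats::cov(yy, zz) / stats::var(zz)
        # variance transmitted by the component, measured the way a
        # variance-component fit measures it: between-level variance of the
        # partial-residual level means minus the pooled (assumed
        # homoscedastic) within-level noise -- censoring curvature and
        # heteroscedasticity then enter here exactly as they enter REML
        rg <- yy - rep(as.numeric(X1 %*% ob), n_rep)
        for (h in seq_len(nG)) {
          if (h != g && s[h] > 0) {
            zh <- unlist(lapply(zg, function(z) z[[h]]), use.names = FALSE)
            rg <- rg - (stats::cov(yy, zh) / stats::var(zh)) * zh
          }
        }
        lev <- rep(groups[[g]], n_rep) +
          rep(seq_len(n_rep) - 1L, each = n) * sizes[g]
        nl <- tabulate(lev)
        ml <- rowsum(rg, lev)[, 1] / nl
        wvar <- sum((rg - ml[lev])^2) / (length(rg) - length(nl))
        v_obs <- max(stats::var(ml) - wvar * mean(1 / nl), 1e-12)
        ratio <- sd_target[g] / sqrt(v_obs)
        s[g] <- s[g] * min(max(ratio, 0.5), 2)^0.6
        s[g] <- min(max(s[g], sd_target[g] / 4), sd_target[g] * 6)
        delta <- max(delta, abs(ratio - 1) * sd_target[g])
      }
      if (resid_target == 0) {
        s[nG + 1] <- 0
      } else {
        expl <- rep(as.numeric(X1 %*% ob), n_rep)
        for (g in seq_len(nG)) {
          zz <- unlist(lapply(zg, function(z) z[[g]]), use.names = FALSE)
          expl <- expl + slopes[g] * zz
        }
        sd_r <- stats::sd(yy - expl)
        ratio <- resid_target / max(sd_r, 1e-6)
        s[nG + 1] <- s[nG + 1] * min(max(ratio, 0.5), 2)^0.6
        s[nG + 1] <- min(max(s[nG + 1], resid_target / 4),
                         resid_target * 6)
        delta <- max(delta, abs(ratio - 1) * resid_target)
      }
      if (delta < tol) break
    }
    list(beta_lat = beta_lat, mu0 = mu0, s = s, kappa = kappa)
  })
}

#' Simulate the weekly pelt-biting monitoring panel
#'
#' Builds the multi-year July-August weekly monitooring panel: per-year
#' single-sex group assignments (group size is the count of animals sharing
#' the group), ages and weights advancing along the growth curve, weekly
#' heat stress from the weather series, and the ordinal pelt-biting class
#' generated from the configured population model (fixed effects on the
#' shared orthonormal basis, crossed animal and year random intercepts,
#' Gaussian residual) with observed-scale calibration of the censored class
#' (see [calibrate_latent()]; disable with `cfg$calibrate = FALSE`).
#'
#' @param roster herd roster from [generate_herd()].
#' @param weather daily weather from [generate_weather()].
#' @param cfg a [generator_config()].
#' @return data frame of monitoring events with attributes `basis`
#'   (the serialized-able [build_basis()] object) and `calibration`.
#' @export
simulate_monitoring <- function(roster, weather, cfg) {
  validate_config(cfg)
  beta <- cfg$coefficients$population
  events <- with_stream(cfg$seed, "monitoring_frame", {
    years <- cfg$start_year + seq_len(cfg$n_years) - 1L
    rows <- list()
    for (y in years) {
      active <- roster[roster$entry_year <= y &
                         roster$entry_year + roster$span > y, ]
      if (nrow(active) < 4L) next
      grp <- character(nrow(active))
      gsz <- integer(nrow(active))
      for (s in c("f", "m")) {
        ids <- active$id[active$sex == s]
        if (length(ids) < 2L * cfg$n_groups_per_sex) {
          grp[active$sex == s] <- sprintf("%sG1-%d", s, y)
          gsz[active$sex == s] <- length(ids)
          next
        }
        groups <- split_groups(ids, cfg$n_groups_per_sex)
        for (g in seq_along(groups)) {
          sel <- active$id %in% groups[[g]]
          grp[sel] <- sprintf("%sG%d-%d", s, g, y)
          gsz[sel] <- length(groups[[g]])
        }
      }
      doys <- 186L + 7L * (seq_len(cfg$weeks_per_season) - 1L)
      for (w in seq_along(doys)) {
        age_now <- active$age_years + (y - active$entry_year)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = active$id, sex = active$sex, year = y, doy = doys[w],
          group_id = grp, group_size = gsz,
          age = age_now,
          weight = growth_curve(age_now, active$sex) + active$weight_dev +
            stats::rnorm(nrow(active), 0, 2),
          dob = active$date_of_birth_doy,
          stringsAsFactors = FALSE
        )
      }
    }
    ev <- do.call(rbind, rows)
    if (cfg$attrition > 0) {
      ev <- ev[stats::runif(nrow(ev)) >= cfg$attrition, ]
    }
    ev
  })
  events$date <- as.Date(sprintf("%d-01-01", events$year)) +
    (events$doy - 1L)

  daily <- thiws_daily(weather)
  daily$doy <- as.integer(format(daily$date, "%j"))
  events$thiws <- mapply(function(y, d) {
    sel <- daily$year == y & daily$doy >= d - 6L & daily$doy <= d
    mean(daily$thiws[sel])
  }, events$year, events$doy)
  if (anyNA(events$thiws)) {
    stop("weather series does not cover the monitoring years")
  }

  basis <- build_basis(events, c(group_size = 2, age = 2, dob = 2,
                                 weight = 2, thiws = 2))
  design <- population_design(events, basis)
  terms <- setdiff(names(beta), "(Intercept)")
  missing <- setdiff(terms, names(design))
  if (length(missing)) {
    stop("configuration error: coefficients reference unknown terms: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(design[terms])
  sd_re <- cfg$re_sd$population[c("animal_id", "year")]
  groups <- list(animal_id = match(events$animal_id,
                                   unique(events$animal_id)),
                 year = match(events$year, sort(unique(events$year))))
  # right-skewed random components: most deer carry few bites, a few are
  # heavily bitten, and the class floor at 1 binds far less often than
  # under Gaussian components of the same SD
  skew_k <- cfg$component_skew_shape
  # random-effect draws are centered across the realized levels: the
  # configured intercept is the study-average level, and the censoring
  # calibration conditions on it
  z_a <- with_stream(cfg$seed, "monitoring_re_animal",
                     qdraw(max(groups$animal_id), skew_k))
  z_y <- with_stream(cfg$seed, "monitoring_re_year",
                     qdraw(max(groups$year), skew_k))
  z_e <- with_stream(cfg$seed, "monitoring_resid",
                     qdraw(nrow(events), skew_k))

  if (cfg$calibrate) {
    cal <- censoring_calibration(X, beta, groups, sd_target = sd_re,
                                 resid_target =
                                   cfg$residual_sd[["population"]],
                                 seed = cfg$seed,
                                 stream = "monitoring_calibration",
                                 skew_k = skew_k)
  } else {
    cal <- list(beta_lat = beta[terms], mu0 = beta[["(Intercept)"]],
                s = c(sd_re, cfg$residual_sd[["population"]]),
                kappa = NA_real_)
  }
  events$pelt_latent <- cal$mu0 + as.numeric(X %*% cal$beta_lat) +
    cal$s[[1]] * z_a[groups$animal_id] + cal$s[[2]] * z_y[groups$year] +
    cal$s[[3]] * z_e
  events$pelt_class <- snap_class(events$pelt_latent)
  rownames(events) <- NULL
  structure(events, basis = basis,
            calibration = cal[c("mu0", "s", "kappa")])
}

#' Simulate the hierarchy observation study
#'
#' Emulates the two-year direct-observation study: adult hinds in several
#' single-sex groups, dyadic agonistic interactions generated from latent
#' dominance propensities, rank orders inferred with Combi1 + I&SI, and a
#' seasonal-mean pelt-biting score per hind-year generated from the
#' configured rank model (raw-scale quadratic in the standardized rank,
#' controlling for age and weight, hind and year random intercepts). The
#' response is a seasonal aggregate, so it is left continuous and only
#' floored at class 1 / capped at 5; the generating rank covariate is the
#' *true* latent order while the `rank` column holds the I&SI estimate used
#' for fitting.
#'
#' @param cfg a [generator_config()].
#' @return data frame (one row per hind-year) with attributes
#'   `interactions` and `ranks`.
#' @export
simulate_hierarchy_panel <- function(cfg) {
  validate_config(cfg)
  beta <- cfg$coefficients$rank
  hinds <- with_stream(cfg$seed, "hierarchy_herd", {
    n <- cfg$hier_n_hinds
    age <- pmin(3 + stats::rgamma(n, shape = 2.5, scale = 1.8), 15)
    dev <- stats::rnorm(n, 0, 6)
    z_age <- as.numeric(scale(age))
    comp <- as.numeric(scale(z_age + stats::rnorm(n, 0, 0.5)))
    rho <- cfg$rank_trait_correlation
    data.frame(
      id = sprintf("H%03d", seq_len(n)), sex = "f",
      age = age, weight_dev = dev,
      latent_rank = rho * comp + sqrt(1 - rho^2) * stats::rnorm(n),
      stringsAsFactors = FALSE
    )
  })

  years <- 2017L + seq_len(cfg$hier_n_years) - 1L
  rows <- list()
  all_int <- list()
  all_ranks <- list()
  for (y in years) {
    assign_y <- with_stream(cfg$seed, paste0("hierarchy_groups_", y), {
      g <- sample(rep(seq_len(cfg$hier_n_groups), length.out = nrow(hinds)))
      sprintf("fH%d-%d", g, y)
    })
    roster_y <- data.frame(
      id = hinds$id, sex = "f", group_id = assign_y,
      latent_rank = hinds$latent_rank, stringsAsFactors = FALSE
    )
    ints <- simulate_interactions(roster_y, cfg, year = y,
                                  stream = "hierarchy_interactions")
    all_int[[as.character(y)]] <- ints
    for (g in unique(roster_y$group_id)) {
      ids <- roster_y$id[roster_y$group_id == g]
      mat <- build_dominance_matrix(ints[ints$group_id == g, ], ids)
      rk <- isi_order(mat, seed = derive_seed(cfg$seed, paste0("isi", g, y)))
      rk$rank_est <- standardize_rank(rk$order_position)
      rk$group_id <- g
      rk$year <- y
      all_ranks[[paste(g, y)]] <- rk

      sub <- hinds[match(ids, hinds$id), ]
      true_pos <- match(seq_along(ids), order(-sub$latent_rank))
      rows[[paste(g, y)]] <- data.frame(
        hind_id = ids, year = y, group_id = g, n_group = length(ids),
        age = sub$age + (y - years[1]),
        weight = growth_curve(sub$age + (y - years[1]), "f") +
          sub$weight_dev,
        rank_true = standardize_rank(true_pos),
        rank = rk$rank_est[match(ids, rk$id)],
        stringsAsFactors = FALSE
      )
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL

  # generation uses the *true* latent order as the rank covariate; the
  # I&SI estimate in `rank` is what the fitter sees (the small
  # errors-in-covariate attenuation this induces is documented in the
  # methods vignette)
  X <- cbind(age.1 = panel$age, weight.1 = panel$weight,
             rank.1 = panel$rank_true, rank.2 = panel$rank_true^2)
  sd_re <- cfg$re_sd$rank[c("hind_id", "year")]
  groups <- list(hind_id = match(panel$hind_id, hinds$id),
                 year = match(panel$year, years))
  # the seasonal-mean response is generated faithfully on the observed
  # scale (Gaussian components by the CLT of a seasonal average, floor at
  # class 1 only); no censoring calibration is applied here because the
  # floor margin left by the predictor is too small for the inverse map to
  # have a stable fixed point -- the resulting floor shrinkage of the
  # raw-scale coefficients is documented in the methods vignette
  z_h <- with_stream(cfg$seed, "hierarchy_re_hind", qdraw(nrow(hinds)))
  z_y <- with_stream(cfg$seed, "hierarchy_re_year", qdraw(length(years)))
  z_e <- with_stream(cfg$seed, "hierarchy_resid", qdraw(nrow(panel)))
  latent <- beta[["(Intercept)"]] +
    as.numeric(X %*% beta[colnames(X)]) +
    sd_re[["hind_id"]] * z_h[groups$hind_id] +
    sd_re[["year"]] * z_y[groups$year] +
    cfg$residual_sd[["rank"]] * z_e
  panel$pelt_score <- pmin(pmax(latent, 1), 5)
  structure(panel,
            interactions = do.call(rbind, all_int),
            ranks = do.call(rbind, all_ranks))
}

#' Simulate the pregnancy (foetus-sex) monitoring panel
#'
#' Hinds carry several pregnancies across the study years; each pregnancy
#' (= one calf) is monitored repeatedly, with `conception_day` counting days
#' after conception at each event and hind weight increasing along
#' gestation. The ordinal pelt class is generated from the configured
#' pregnancy model (cubic orthonormal polynomials, male-foetus indicator and
#' conception-day-by-foetus-sex interactions, crossed calf/hind/year random
#' intercepts) with the same observed-scale calibration as the monitoring
#' panel.
#'
#' @param cfg a [generator_config()].
#' @return data frame of pregnancy monitoring events with attributes
#'   `basis` and `calibration`.
#' @export
simulate_pregnancy_panel <- function(cfg) {
  validate_config(cfg)
  beta <- cfg$coefficients$pregnancy
  panel <- with_stream(cfg$seed, "pregnancy_frame", {
    n <- cfg$preg_n_hinds
    base_age <- pmin(2 + stats::rgamma(n, shape = 2, scale = 1.5), 12)
    dev <- stats::rnorm(n, 0, 6)
    rows <- list()
    calf_no <- 0L
    for (h in seq_len(n)) {
      n_preg <- min(1L + stats::rpois(1, cfg$preg_mean_pregnancies - 1),
                    cfg$n_years)
      yrs <- sort(sample(cfg$n_years, n_preg))
      for (k in seq_along(yrs)) {
        calf_no <- calf_no + 1L
        year <- cfg$start_year + yrs[k] - 1L
        age <- base_age[h] + (yrs[k] - yrs[1])
        cd <- 40 + 13 * (seq_len(cfg$preg_events) - 1)
        rows[[calf_no]] <- data.frame(
          hind_id = sprintf("P%03d", h),
          calf_id = sprintf("C%04d", calf_no),
          year = year,
          foetus_sex = sample(c("f", "m"), 1),
          conception_day = cd,
          hind_age = age,
          hind_weight = growth_curve(age, "f") + dev[h] + 0.09 * cd +
            stats::rnorm(length(cd), 0, 2),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  rownames(panel) <- NULL

  basis <- build_basis(panel, c(hind_age = 3, hind_weight = 3,
                                conception_day = 3))
  design <- pregnancy_design(panel, basis)
  terms <- setdiff(names(beta), "(Intercept)")
  missing <- setdiff(terms, names(design))
  if (length(missing)) {
    stop("configuration error: coefficients reference unknown terms: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(design[terms])
  sd_re <- cfg$re_sd$pregnancy[c("calf_id", "hind_id", "year")]
  groups <- list(calf_id = match(panel$calf_id, unique(panel$calf_id)),
                 hind_id = match(panel$hind_id, unique(panel$hind_id)),
                 year = match(panel$year, sort(unique(panel$year))))
  skew_k <- cfg$component_skew_shape
  z_c <- with_stream(cfg$seed, "pregnancy_re_calf",
                     qdraw(max(groups$calf_id), skew_k))
  z_h <- with_stream(cfg$seed, "pregnancy_re_hind",
                     qdraw(max(groups$hind_id), skew_k))
  z_y <- with_stream(cfg$seed, "pregnancy_re_year",
                     qdraw(max(groups$year), skew_k))
  z_e <- with_stream(cfg$seed, "pregnancy_resid",
                     qdraw(nrow(panel), skew_k))

  if (cfg$calibrate) {
    cal <- censoring_calibration(X, beta, groups, sd_target = sd_re,
                                 resid_target =
                                   cfg$residual_sd[["pregnancy"]],
                                 seed = cfg$seed,
                                 stream = "pregnancy_calibration",
                                 skew_k = skew_k)
  } else {
    cal <- list(beta_lat = beta[terms], mu0 = beta[["(Intercept)"]],
                s = c(sd_re, cfg$residual_sd[["pregnancy"]]),
                kappa = NA_real_)
  }
  panel$pelt_latent <- cal$mu0 + as.numeric(X %*% cal$beta_lat) +
    cal$s[[1]] * z_c[groups$calf_id] + cal$s[[2]] * z_h[groups$hind_id] +
    cal$s[[3]] * z_y[groups$year] + cal$s[[4]] * z_e
  panel$pelt_class <- snap_class(panel$pelt_latent)
  structure(panel, basis = basis,
            calibration = cal[c("mu0", "s", "kappa")])
}
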