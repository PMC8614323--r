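#' Default fixed-effect coefficients of the population pelt-biting model
#'
#' Named vector of coefficients, on the shared orthonormal basis, of the
#' weekly-monitoring model: polynomial (degree 2) terms for group size, age,
#' day-of-year of birth, body weight and seasonal heat stress (THIWS), a
#' male indicator (female reference) and male-by-covariate interactions.
#' Term names follow `<covariate>.<degree>` with `_x_sex_m` marking
#' interactions.
#'
#' @return named numeric vector including `"(Intercept)"`.
#' @export
population_coefficients <- function() {
  c(
    "(Intercept)" = 1.35,
    group_size.1 = 8.36, group_size.2 = -3.22,
    age.1 = 9.85, age.2 = -11.85,
    sex_m = 0.18,
    dob.1 = 8.49, dob.2 = -6.37,
    weight.1 = -35.75, weight.2 = -35.64,
    thiws.1 = 3.84, thiws.2 = -0.12,
    age.1_x_sex_m = 4.30, age.2_x_sex_m = -4.34,
    weight.1_x_sex_m = 26.04, weight.2_x_sex_m = 29.54,
    thiws.1_x_sex_m = -0.91, thiws.2_x_sex_m = -1.73
  )
}

#' Default coefficients of the hierarchy-rank pelt-biting model
#'
#' Raw-scale coefficients of the hind hierarchy model: age (years), body
#' weight (kg), and a quadratic in the standardized rank covariate
#' (+1 = most dominant, -1 = least dominant; see [standardize_rank()]).
#'
#' @return named numeric vector including `"(Intercept)"`.
#' @export
rank_coefficients <- function() {
  c(
    "(Intercept)" = 1.817,
    age.1 = -0.008,
    weight.1 = -0.005,
    rank.1 = -0.495,
    rank.2 = -0.257
  )
}

#' Default coefficients of the pregnancy (foetus-sex) pelt-biting model
#'
#' Orthonormal-basis coefficients of the pregnancy model: cubic polynomials
#' in hind age, hind weight and days after conception, a male-foetus
#' indicator, and male-foetus-by-conception-day interactions.
#'
#' @return named numeric vector including `"(Intercept)"`.
#' @export
pregnancy_coefficients <- function() {
  c(
    "(Intercept)" = 1.49,
    hind_age.1 = -2.00, hind_age.2 = 2.18, hind_age.3 = 0.37,
    hind_weight.1 = -23.60, hind_weight.2 = 7.20, hind_weight.3 = -1.14,
    conception_day.1 = 19.78, conception_day.2 = -8.56,
    conception_day.3 = -12.08,
    sex_m = 0.02,
    conception_day.1_x_sex_m = -0.18, conception_day.2_x_sex_m = 0.56,
    conception_day.3_x_sex_m = -2.33
  )
}

#' Configuration of the synthetic deer-farm generator
#'
#' Bundles every tunable of the synthetic study system. Defaults encode the
#' published study conditions: a 14-year weekly monitoring programme
#' (2006-2019) of ~510 animals yielding ~8,000 July-August events, a
#' two-year hierarchy observation study (scaled to 200 hinds for power),
#' a multi-pregnancy panel with crossed calf/hind/year effects, and the
#' fitted model coefficients and variance components as generating values.
#'
#' @param n_females,n_males roster sizes.
#' @param n_years,start_year study window.
#' @param n_groups_per_sex single-sex groups per year (2-6).
#' @param field_area_ha field size per group (hectares).
#' @param weeks_per_season weekly handling events per animal per active year
#'   (July-August window).
#' @param mean_presence_weights probabilities that an animal stays 1-4 years.
#' @param attrition weekly probability that an event is missed.
#' @param coefficients named list with elements `population`, `rank`,
#'   `pregnancy` (named coefficient vectors).
#' @param re_sd named list of random-effect SD vectors per model.
#' @param residual_sd named vector of residual SDs per model.
#' @param rank_trait_correlation correlation between the latent dominance
#'   propensity and the age/weight composite, in `[-1, 1]`.
#' @param interaction_steepness logistic slope of win probability on the
#'   latent-rank difference (> 0).
#' @param interactions_per_dyad mean agonistic interactions recorded per
#'   within-group dyad (the published study observed ~11 per dyad).
#' @param hier_n_hinds,hier_n_years,hier_n_groups hierarchy-study design.
#' @param preg_n_hinds,preg_mean_pregnancies,preg_events pregnancy-panel
#'   design.
#' @param weather_params seasonal means/SDs for temperature (degrees C),
#'   relative humidity (percent), wind (m/s) and solar radiation (MJ/m^2);
#'   `amp` entries give the within-season sinusoidal amplitude.
#' @param component_skew_shape gamma shape of the standardized random
#'   components of the class panels (smaller = more right-skewed; `NULL`
#'   for Gaussian components).
#' @param calibrate logical: calibrate discretized panels to the observed
#'   scale (see the methods vignette).
#' @param seed master seed; every generator draws from a named substream of
#'   it.
#' @return an object of class `pb_config` (a validated list).
#' @export
generator_config <- function(n_females = 265L,
                             n_males = 245L,
                             n_years = 14L,
                             start_year = 2006L,
                             n_groups_per_sex = 3L,
                             field_area_ha = 0.9,
                             weeks_per_season = 9L,
                             mean_presence_weights = c(0.55, 0.25, 0.12, 0.08),
                             attrition = 0,
                             coefficients = list(
                               population = population_coefficients(),
                               rank = rank_coefficients(),
                               pregnancy = pregnancy_coefficients()
                             ),
                             re_sd = list(
                               population = c(animal_id = 0.269, year = 0.255),
                               rank = c(hind_id = 0.142, year = 0.112),
                               pregnancy = c(calf_id = 0.212, hind_id = 0.325,
                                             year = 0.253)
                             ),
                             residual_sd = c(population = 0.426, rank = 0.087,
                                             pregnancy = 0.430),
                             rank_trait_correlation = 0.5,
                             interaction_steepness = 1.5,
                             interactions_per_dyad = 11,
                             hier_n_hinds = 200L,
                             hier_n_years = 2L,
                             hier_n_groups = 10L,
                             preg_n_hinds = 58L,
                             preg_mean_pregnancies = 3.7,
                             preg_events = 14L,
                             weather_params = list(
                               T = list(mean = 24.5, year_sd = 1,
                                        day_sd = 2.5, amp = 3),
                               Hr = list(mean = 45, year_sd = 4, day_sd = 8),
                               W = list(mean = 2.5, year_sd = 0.3, day_sd = 1),
                               SR = list(mean = 26, year_sd = 0.8, day_sd = 3,
                                         amp = 3)
                             ),
                             component_skew_shape = 2,
                             calibrate = TRUE,
                             seed = 1L) {
  cfg <- list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    n_groups_per_sex = as.integer(n_groups_per_sex),
    field_area_ha = field_area_ha,
    weeks_per_season = as.integer(weeks_per_season),
    mean_presence_weights = mean_presence_weights,
    attrition = attrition,
    coefficients = coefficients, re_sd = re_sd, residual_sd = residual_sd,
    rank_trait_correlation = rank_trait_correlation,
    interaction_steepness = interaction_steepness,
    interactions_per_dyad = interactions_per_dyad,
    hier_n_hinds = as.integer(hier_n_hinds),
    hier_n_years = as.integer(hier_n_years),
    hier_n_groups = as.integer(hier_n_groups),
    preg_n_hinds = as.integer(preg_n_hinds),
    preg_mean_pregnancies = preg_mean_pregnancies,
    preg_events = as.integer(preg_events),
    weather_params = weather_params,
    component_skew_shape = component_skew_shape,
    calibrate = isTRUE(calibrate),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pb_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_years >= 1L, cfg$weeks_per_season >= 1L)
  if (cfg$n_groups_per_sex < 2L || cfg$n_groups_per_sex > 6L) {
    stop("n_groups_per_sex must lie in [2, 6]")
  }
  if (cfg$n_females < 2L * cfg$n_groups_per_sex ||
      cfg$n_males < 2L * cfg$n_groups_per_sex) {
    stop("each single-sex group needs at least 2 animals")
  }
  if (abs(cfg$rank_trait_correlation) > 1) {
    stop("rank_trait_correlation must lie in [-1, 1]")
  }
  if (cfg$interaction_steepness <= 0) stop("interaction_steepness must be > 0")
  if (any(unlist(cfg$re_sd) < 0)) stop("random-effect SDs must be >= 0")
  if (any(cfg$residual_sd < 0)) stop("residual SDs must be >= 0")
  if (cfg$attrition < 0 || cfg$attrition >= 1) stop("attrition must be in [0, 1)")
  invisible(cfg)
}

#' Read or write a generator configuration as JSON
#'
#' @param cfg a `pb_config`.
#' @param path file path.
#' @return `read_config()` returns a `pb_config`; `write_config()` its path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pb_config"))
  ser <- unclass(cfg)
  # named numeric vectors must become JSON objects, not bare arrays
  ser$coefficients <- lapply(ser$coefficients, as.list)
  ser$re_sd <- lapply(ser$re_sd, as.list)
  ser$residual_sd <- as.list(ser$residual_sd)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$coefficients <- lapply(raw$coefficients, unlist)
  raw$re_sd <- lapply(raw$re_sd, unlist)
  raw$residual_sd <- unlist(raw$residual_sd)
  do.call(generator_config, raw)
}
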