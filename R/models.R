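#' Design columns of the population pelt-biting model
#'
#' Expands a monitoring panel into the fixed-effect design of the weekly
#' population model: degree-2 orthonormal polynomial columns for group
#' size, age, day-of-year of birth, body weight and weekly heat stress; a
#' male indicator (`sex_m`, female reference); and male-by-age, male-by-
#' weight and male-by-heat-stress product columns.
#'
#' @param data monitoring panel (needs `group_size`, `age`, `dob`,
#'   `weight`, `thiws`, `sex`).
#' @param basis a [build_basis()] object for the five covariates.
#' @return data frame of design columns.
#' @export
population_design <- function(data, basis) {
  U <- apply_basis(basis, data)
  U$sex_m <- as.numeric(data$sex == "m")
  for (cov in c("age", "weight", "thiws")) {
    for (d in 1:2) {
      main <- sprintf("%s.%d", cov, d)
      U[[sprintf("%s_x_sex_m", main)]] <- U[[main]] * U$sex_m
    }
  }
  U
}

#' Design columns of the pregnancy model
#'
#' Degree-3 orthonormal polynomial columns for hind age, hind weight and
#' days after conception, a male-foetus indicator, and conception-day-by-
#' foetus-sex product columns.
#'
#' @param data pregnancy panel (needs `hind_age`, `hind_weight`,
#'   `conception_day`, `foetus_sex`).
#' @param basis a [build_basis()] object for the three covariates.
#' @return data frame of design columns.
#' @export
pregnancy_design <- function(data, basis) {
  U <- apply_basis(basis, data)
  U$sex_m <- as.numeric(data$foetus_sex == "m")
  for (d in 1:3) {
    main <- sprintf("conception_day.%d", d)
    U[[sprintf("%s_x_sex_m", main)]] <- U[[main]] * U$sex_m
  }
  U
}

#' Design columns of the hierarchy-rank model (raw scale)
#'
#' The hierarchy model is reported on raw covariate scales: age in years,
#' weight in kg, and a quadratic in the standardized rank.
#'
#' @param data hierarchy panel (needs `age`, `weight`, `rank`).
#' @return data frame with columns `age.1`, `weight.1`, `rank.1`, `rank.2`.
#' @export
rank_design <- function(data) {
  data.frame(
    age.1 = data$age, weight.1 = data$weight,
    rank.1 = data$rank, rank.2 = data$rank^2
  )
}

#' Fit the population pelt-biting model to a monitoring panel
#'
#' Rebuilds (or reuses) the shared orthonormal basis on the panel, expands
#' the design and fits the full polynomial model with crossed animal and
#' year random intercepts to the ordinal pelt class.
#'
#' @param panel monitoring panel from [simulate_monitoring()] (or real data
#'   with the same columns).
#' @param basis optional stored basis; by default the basis attached to the
#'   panel, else rebuilt from the panel.
#' @return a `pb_fit` with the basis in `$basis`.
#' @export
fit_population_model <- function(panel, basis = NULL) {
  basis <- basis %||% attr(panel, "basis") %||%
    build_basis(panel, c(group_size = 2, age = 2, dob = 2, weight = 2,
                         thiws = 2))
  d <- population_design(panel, basis)
  d$pelt_class <- panel$pelt_class
  d$animal_id <- panel$animal_id
  d$year <- factor(panel$year)
  terms <- setdiff(names(population_coefficients()), "(Intercept)")
  fit <- fit_lmm(d, "pelt_class", terms, c("animal_id", "year"))
  fit$basis <- basis
  fit
}

#' Fit the hierarchy-rank model to a hierarchy panel
#'
#' Quadratic in the (estimated) standardized rank, controlling for hind age
#' and weight, with hind and year random intercepts; raw covariate scales.
#'
#' @param panel hierarchy panel from [simulate_hierarchy_panel()].
#' @return a `pb_fit`.
#' @export
fit_rank_model <- function(panel) {
  d <- rank_design(panel)
  d$pelt_score <- panel$pelt_score
  d$hind_id <- panel$hind_id
  d$year <- factor(panel$year)
  fit_lmm(d, "pelt_score", c("age.1", "weight.1", "rank.1", "rank.2"),
          c("hind_id", "year"))
}

#' Fit the pregnancy model to a pregnancy panel
#'
#' Cubic orthonormal polynomials for hind age, hind weight and days after
#' conception, foetus-sex indicator and its conception-day interactions,
#' with crossed calf/hind/year random intercepts.
#'
#' @param panel pregnancy panel from [simulate_pregnancy_panel()].
#' @param basis optional stored basis (default: the panel attribute).
#' @return a `pb_fit` with the basis in `$basis`.
#' @export
fit_pregnancy_model <- function(panel, basis = NULL) {
  basis <- basis %||% attr(panel, "basis") %||%
    build_basis(panel, c(hind_age = 3, hind_weight = 3, conception_day = 3))
  d <- pregnancy_design(panel, basis)
  d$pelt_class <- panel$pelt_class
  d$calf_id <- panel$calf_id
  d$hind_id <- panel$hind_id
  d$year <- factor(panel$year)
  terms <- setdiff(names(pregnancy_coefficients()), "(Intercept)")
  fit <- fit_lmm(d, "pelt_class", terms, c("calf_id", "hind_id", "year"))
  fit$basis <- basis
  fit
}

#' Term table of the population model for backward elimination
#'
#' @return data frame with columns `term`, `interaction`, `family`,
#'   `degree` describing the full population model, as needed by
#'   [backward_eliminate()].
#' @export
population_terms <- function() {
  nm <- setdiff(names(population_coefficients()), "(Intercept)")
  inter <- grepl("_x_sex_m$", nm)
  main <- sub("_x_sex_m$", "", nm)
  deg <- ifelse(grepl("\\.\\d$", main), as.integer(sub(".*\\.", "", main)),
                0L)
  fam <- ifelse(inter, paste0(sub("\\.\\d$", "", main), ":sex_m"),
                sub("\\.\\d$", "", main))
  data.frame(term = nm, interaction = inter, family = fam, degree = deg,
             stringsAsFactors = FALSE)
}
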