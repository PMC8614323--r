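#' Fit a linear mixed model with crossed random intercepts
#'
#' REML fit of `response ~ fixed terms + (1 | factor) + ...` where every
#' fixed term is a prebuilt design column (basis column, indicator, or
#' product column), so polynomial degrees and interactions are individual,
#' testable coefficients, as the pelt-biting models report them. The design
#' is rank-checked first (a singular design raises an error naming the
#' collinear columns). Estimation is delegated to `lmer`; per-coefficient
#' denominator degrees of freedom and p-values use the Satterthwaite
#' approximation, falling back to the residual df (flagged in the table)
#' when the variance-component covariance is unavailable.
#'
#' @param data data frame holding the design columns, the response and the
#'   random-effect factors.
#' @param response name of the response column.
#' @param fixed_terms character vector of design-column names.
#' @param re_factors character vector of random-intercept factor columns
#'   (crossed, not nested).
#' @param reml logical, REML (default) or ML.
#' @return an object of class `pb_fit`: list with `coefficients` (term,
#'   estimate, se, df, t, p, df_method), `re_sd`, `residual_sd`, `n`,
#'   `r2_marginal`, `r2_conditional`, `converged`, `singular`, and the
#'   underlying `merMod` in `$fit`.
#' @export
fit_lmm <- function(data, response, fixed_terms, re_factors, reml = TRUE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  miss <- setdiff(c(fixed_terms, re_factors), names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  for (f in re_factors) {
    if (length(unique(data[[f]])) < 2L) {
      stop("random factor `", f, "` needs at least 2 levels")
    }
  }
  n <- nrow(data)
  p <- length(fixed_terms) + 1L
  if (n <= p) stop("more fixed effects than observations")

  X <- cbind(`(Intercept)` = 1, as.matrix(data[fixed_terms]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }

  fx <- paste(sprintf("`%s`", fixed_terms), collapse = " + ")
  rx <- paste(sprintf("(1 | %s)", re_factors), collapse = " + ")
  form <- stats::as.formula(paste0("`", response, "` ~ ", fx, " + ", rx))
  fit <- lmerTest::lmer(form, data = data, REML = reml,
                        control = lme4::lmerControl(calc.derivs = FALSE))

  smr <- tryCatch(summary(fit, ddf = "Satterthwaite")$coefficients,
                  error = function(e) NULL)
  resid_df <- n - p
  if (is.null(smr) || !"df" %in% colnames(smr)) {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    tab <- data.frame(
      term = names(est), estimate = as.numeric(est), se = se,
      df = resid_df, t = as.numeric(est) / se, df_method = "residual",
      row.names = NULL
    )
    tab$p <- 2 * stats::pt(-abs(tab$t), tab$df)
  } else {
    tab <- data.frame(
      term = rownames(smr), estimate = smr[, "Estimate"],
      se = smr[, "Std. Error"], df = smr[, "df"], t = smr[, "t value"],
      p = smr[, "Pr(>|t|)"], df_method = "satterthwaite", row.names = NULL
    )
    bad <- !is.finite(tab$df) | tab$df <= 0
    if (any(bad)) {
      tab$df[bad] <- resid_df
      tab$p[bad] <- 2 * stats::pt(-abs(tab$t[bad]), resid_df)
      tab$df_method[bad] <- "residual"
    }
  }
  tab$term[tab$term == "(Intercept)"] <- "(Intercept)"
  tab$term <- gsub("`", "", tab$term)

  vc <- lme4::VarCorr(fit)
  re_sd <- vapply(vc, function(m) attr(m, "stddev")[[1]], 0)
  res <- list(
    coefficients = tab,
    re_sd = re_sd,
    residual_sd = stats::sigma(fit),
    n = n,
    converged = length(fit@optinfo$conv$lme4$messages) == 0L,
    singular = lme4::isSingular(fit),
    formula = form,
    fit = fit
  )
  r2 <- r2_nakagawa_components(fit)
  res$r2_marginal <- r2[["r2m"]]
  res$r2_conditional <- r2[["r2c"]]
  class(res) <- "pb_fit"
  res
}

#' @export
print.pb_fit <- function(x, ...) {
  cat("Linear mixed model (", x$n, " obs)\n", sep = "")
  cat("Random-effect SDs:\n")
  print(round(c(x$re_sd, residual = x$residual_sd), 4))
  cat("Fixed effects:\n")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$df <- round(tab$df, 1)
  tab$t <- round(tab$t, 3)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "estimate", "se", "df", "t", "p")],
        row.names = FALSE)
  cat(sprintf("R2 marginal = %.3f, R2 conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Satterthwaite denominator degrees of freedom of one coefficient
#'
#' @param fit a `pb_fit`.
#' @param term coefficient name (as in `fit$coefficients$term`).
#' @return the approximate denominator df (attribute `method` records
#'   whether the Satterthwaite machinery or the residual-df fallback was
#'   used).
#' @export
satterthwaite_df <- function(fit, term) {
  stopifnot(inherits(fit, "pb_fit"))
  tab <- fit$coefficients
  k <- match(term, tab$term)
  if (is.na(k)) stop("unknown term `", term, "`")
  structure(tab$df[k], method = tab$df_method[k])
}

r2_nakagawa_components <- function(fit) {
  X <- lme4::getME(fit, "X")
  eta <- as.numeric(X %*% lme4::fixef(fit))
  var_f <- mean((eta - mean(eta))^2)
  vc <- lme4::VarCorr(fit)
  var_re <- sum(vapply(vc, function(m) attr(m, "stddev")[[1]]^2, 0))
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_re + var_e
  c(r2m = var_f / tot, r2c = (var_f + var_re) / tot)
}

#' Nakagawa marginal and conditional R-squared
#'
#' `R2_marginal` is the variance of the fixed-effect linear predictor over
#' the observations divided by the total (fixed + random-intercept +
#' residual) variance; `R2_conditional` adds the random-effect variances to
#' the numerator. Both are bounded by `0 <= R2m <= R2c <= 1`.
#'
#' @param fit a `pb_fit` (or a fitted `merMod`).
#' @return named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  m <- if (inherits(fit, "pb_fit")) fit$fit else fit
  r2 <- r2_nakagawa_components(m)
  c(r2_marginal = r2[["r2m"]], r2_conditional = r2[["r2c"]])
}

#' Backward elimination of non-significant interactions under marginality
#'
#' Starting from the full model, repeatedly refits and removes the least
#' significant *removable* interaction term with p > alpha. A term is
#' removable only if no higher-degree interaction of the same
#' covariate-by-factor family remains in the model (the marginality
#' principle); main effects are never tested or removed while any of their
#' interactions remain, and are retained throughout, as the published
#' analysis kept the main structure and pruned interactions only.
#'
#' @param data design data frame (see [fit_lmm()]).
#' @param response response column name.
#' @param terms data frame with columns `term`, `interaction` (logical),
#'   `family` (e.g. `"weight:sex_m"`) and `degree`; one row per fixed term.
#' @param re_factors random-intercept factors.
#' @param alpha significance threshold (default 0.05).
#' @return list with `terms` (the retained term table), `fit` (final
#'   `pb_fit`) and `log` (one row per elimination step).
#' @export
backward_eliminate <- function(data, response, terms, re_factors,
                               alpha = 0.05) {
  stopifnot(all(c("term", "interaction", "family", "degree") %in%
                  names(terms)))
  cur <- terms
  log <- list()
  step <- 0L
  repeat {
    fit <- fit_lmm(data, response, cur$term, re_factors)
    tab <- fit$coefficients
    keep_int <- cur[cur$interaction, , drop = FALSE]
    if (nrow(keep_int) == 0L) break
    removable <- vapply(seq_len(nrow(keep_int)), function(i) {
      fam <- keep_int$family[i]
      deg <- keep_int$degree[i]
      !any(keep_int$family == fam & keep_int$degree > deg)
    }, TRUE)
    cand <- keep_int[removable, , drop = FALSE]
    cand$p <- tab$p[match(cand$term, tab$term)]
    worst <- cand[which.max(cand$p), , drop = FALSE]
    if (nrow(worst) == 0L || worst$p <= alpha) break
    step <- step + 1L
    log[[step]] <- data.frame(step = step, removed = worst$term,
                              p = worst$p)
    cur <- cur[cur$term != worst$term, , drop = FALSE]
  }
  list(
    terms = cur,
    fit = fit,
    log = if (length(log)) do.call(rbind, log) else
      data.frame(step = integer(0), removed = character(0), p = numeric(0))
  )
}
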