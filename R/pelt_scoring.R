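#' Pelt-biting class scale
#'
#' Percent-of-pelt-surface thresholds delimiting the five ordinal main
#' classes: class 1 = `[0, 3]`%, class 2 = `(3, 10]`%, class 3 = `(10, 40]`%,
#' class 4 = `(40, 70]`%, class 5 = `(70, 100]`%. Each main class is further
#' subdivided into quartiles, giving the 0.25-step ordinal grid
#' 1.00, 1.25, ..., 5.00.
#'
#' @format A numeric vector of interior boundaries (percent).
#' @export
pelt_class_boundaries <- c(3, 10, 40, 70)

#' Map percent of pelt surface bitten to the ordinal class
#'
#' The main class is chosen by the interval containing `p` (a percent exactly
#' on a boundary belongs to the lower class, matching the half-open
#' `(a, b]` notation of the scale). The fractional part is the position of
#' `p` within its interval floored to quartile steps, so e.g. 25% into the
#' class-2 interval scores 2.25. Class 5 saturates at 5.00, the top of the
#' scale.
#'
#' @param p numeric vector of percentages in `[0, 100]`.
#' @return numeric vector of ordinal classes on the 0.25 grid.
#' @examples
#' percent_to_class(c(0, 4.75, 55))
#' @export
percent_to_class <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    stop("`p` must be finite numeric")
  }
  if (any(p < 0 | p > 100)) {
    stop("percent bitten must lie in [0, 100]")
  }
  lower <- c(0, pelt_class_boundaries)
  upper <- c(pelt_class_boundaries, 100)
  # interval index: p on a boundary stays in the lower class
  k <- findInterval(p, lower, left.open = TRUE) # 0 for p = 0
  k[p == 0] <- 1L
  frac <- (p - lower[k]) / (upper[k] - lower[k])
  quart <- pmin(floor(frac * 4), 3) / 4
  cls <- k + quart
  pmin(cls, 5)
}

#' Clamp and snap a continuous latent score to the ordinal grid
#'
#' Discretizes the continuous latent pelt-biting response the way the field
#' scale records it: clamp to `[1, 5]`, then round (half up) to the nearest
#' 0.25 step.
#'
#' @param latent numeric vector.
#' @return numeric vector on the grid `{1.00, 1.25, ..., 5.00}`.
#' @export
snap_class <- function(latent) {
  x <- pmin(pmax(latent, 1), 5)
  # round half up on the quarter grid
  pmin(pmax(floor(x * 4 + 0.5) / 4, 1), 5)
}

#' Summary statistics of pelt-biting classes
#'
#' Mean, median, quartiles and range of the ordinal class, per sex and
#' pooled, as reported in descriptive analyses of pelt-biting monitoring.
#'
#' @param events data frame with columns `pelt_class` and `sex`
#'   (`"f"`/`"m"`).
#' @return data frame with one row per sex plus a `"pooled"` row.
#' @export
summarize_classes <- function(events) {
  if (!is.data.frame(events) || nrow(events) == 0L) {
    stop("`events` must be a non-empty data frame")
  }
  if (!all(c("pelt_class", "sex") %in% names(events))) {
    stop("`events` needs columns `pelt_class` and `sex`")
  }
  one <- function(x, label) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(
      sex = label, n = length(x), mean = mean(x), median = q[2],
      q1 = q[1], q3 = q[3], min = min(x), max = max(x)
    )
  }
  groups <- split(events$pelt_class, events$sex)
  out <- do.call(rbind, Map(one, groups, names(groups)))
  out <- rbind(out, one(events$pelt_class, "pooled"))
  rownames(out) <- NULL
  out
}
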