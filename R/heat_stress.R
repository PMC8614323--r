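#' THIWS heat-stress index
#'
#' Temperature-humidity index extended with wind speed and solar radiation,
#' used to quantify heat load on outdoor-kept red deer:
#'
#' \deqn{THIWS = 4.51 + 0.8 T + 0.01 Hr (T - 14.4) + 46.4 - 1.992 W +
#'   1.887 SR}
#'
#' The humidity term vanishes at T = 14.4 degrees C; wind cools (negative
#' coefficient) and solar radiation heats. The index is affine in each
#' argument.
#'
#' @param T daily mean air temperature (degrees C).
#' @param Hr mean relative humidity (percent, in `[0, 100]`).
#' @param W mean wind speed (m s^-1, non-negative).
#' @param SR solar radiation accumulated over 24 h (MJ m^-2, non-negative).
#' @return numeric vector of index values.
#' @examples
#' thiws(T = 14.4, Hr = 80, W = 0, SR = 0) # 62.43
#' @export
thiws <- function(T, Hr, W, SR) {
  args <- cbind(T, Hr, W, SR) # recycles and validates lengths
  if (anyNA(args) || any(!is.finite(args))) stop("inputs must be finite")
  T <- args[, 1]; Hr <- args[, 2]; W <- args[, 3]; SR <- args[, 4]
  if (any(Hr < 0 | Hr > 100)) stop("relative humidity must lie in [0, 100]")
  if (any(W < 0)) stop("wind speed must be non-negative")
  if (any(SR < 0)) stop("solar radiation must be non-negative")
  as.numeric(4.51 + 0.8 * T + 0.01 * Hr * (T - 14.4) + 46.4 - 1.992 * W +
               1.887 * SR)
}

#' Daily THIWS records from a weather table
#'
#' @param weather data frame with columns `date`, `T`, `Hr`, `W`, `SR`
#'   (see [generate_weather()]).
#' @return data frame with columns `date`, `year`, `thiws`.
#' @export
thiws_daily <- function(weather) {
  need <- c("date", "T", "Hr", "W", "SR")
  if (!all(need %in% names(weather))) {
    stop("`weather` needs columns ", paste(need, collapse = ", "))
  }
  date <- as.Date(weather$date)
  data.frame(
    date = date,
    year = as.integer(format(date, "%Y")),
    thiws = thiws(weather$T, weather$Hr, weather$W, weather$SR)
  )
}

#' Seasonal (July-August) mean THIWS for one year
#'
#' Aggregates daily index values to the scalar seasonal heat-stress covariate
#' of a year: the arithmetic mean over July and August, the window the
#' weather series covers.
#'
#' @param days data frame with columns `date` and `thiws`.
#' @param year calendar year to aggregate.
#' @return a single numeric value.
#' @export
seasonal_thiws <- function(days, year) {
  date <- as.Date(days$date)
  keep <- as.integer(format(date, "%Y")) == year &
    format(date, "%m") %in% c("07", "08")
  if (!any(keep)) stop("no July-August records for year ", year)
  mean(days$thiws[keep])
}

#' Seasonal THIWS table for all years in a weather series
#'
#' @param weather daily weather data frame.
#' @return data frame with columns `year`, `thiws_mean`.
#' @export
seasonal_thiws_table <- function(weather) {
  daily <- thiws_daily(weather)
  years <- sort(unique(daily$year))
  data.frame(
    year = years,
    thiws_mean = vapply(years, function(y) seasonal_thiws(daily, y), 0)
  )
}
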