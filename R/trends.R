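#' Indices whose log-scale trend uses the +0.5 count offset
#'
#' The four species-count indices may legitimately be zero, so their log
#' trends are fitted on log(count + 0.5); all other indices are fitted on
#' the plain logarithm, and a non-positive value excludes the record.
#' @keywords internal
count_offset_indices <- c("n_threatened", "n_nonnative", "n_specialist",
                          "n_generalist")

#' Fit the trend of one diversity index within one time series
#'
#' Ordinary least squares of (log-transformed) index value on calendar year.
#' On the log scale the slope is reported as annual percentage change,
#' \eqn{(e^{slope} - 1) \cdot 100}; with exactly two observations the slope
#' is the difference quotient. Repeated years (N-to-N designs) enter as
#' repeated x-values.
#'
#' @param years integer calendar years.
#' @param values index values (non-missing).
#' @param scale `"log"` or `"raw"`.
#' @param offset additive constant applied before the log transform
#'   (0.5 for the four species-count indices, otherwise 0).
#' @return list with `n_obs`, `span`, `slope`, `pct_per_year` (log scale
#'   only), `weight` (= ln n_obs), and `reason` (NA when fitted).
#' @examples
#' fit_series_trend(c(2000, 2010), c(10, 20))$pct_per_year # ~7.18 %/yr
#' @export
fit_series_trend <- function(years, values, scale = c("log", "raw"),
                             offset = 0) {
  scale <- match.arg(scale)
  keep <- !is.na(values) & !is.na(years)
  years <- years[keep]; values <- values[keep]
  n <- length(values)
  base <- list(n_obs = n, span = if (n) diff(range(years)) else NA_real_,
               slope = NA_real_, pct_per_year = NA_real_,
               weight = if (n >= 2L) log(n) else NA_real_,
               reason = NA_character_)
  if (length(unique(years)) < 2L) {
    base$reason <- "fewer_than_2_distinct_years"
    return(base)
  }
  y <- values
  if (scale == "log") {
    y <- values + offset
    if (any(y <= 0)) {
      base$reason <- "nonpositive_on_log_scale"
      return(base)
    }
    y <- log(y)
  }
  xc <- years - mean(years)
  # a constant response has slope exactly zero (avoids the O(eps) residual
  # of the centred cross product on >2 support points)
  slope <- if (max(y) == min(y)) 0 else sum(xc * y) / sum(xc^2)
  base$slope <- slope
  if (scale == "log") base$pct_per_year <- (exp(slope) - 1) * 100
  base
}

#' Fit trends for every series and index of a diversity table
#'
#' One ordinary least squares fit per (series, index, scale); observations
#' whose value is missing for an index are dropped for that index only, and
#' exclusions (too few distinct years, non-positive value on the log scale)
#' are recorded rather than erroring.
#'
#' @param diversity output of [compute_diversity()] (columns `obs_id`,
#'   `series_id`, `year`, plus index columns).
#' @param indices index columns to fit; default: every numeric column
#'   except the identifiers.
#' @param scales `"log"`, `"raw"`, or both (default both).
#' @return data frame with one row per series x index x scale: `series_id`,
#'   `index`, `scale`, `n_obs`, `span`, `slope`, `pct_per_year`, `weight`,
#'   `reason`.
#' @export
compute_all_trends <- function(diversity, indices = NULL,
                               scales = c("log", "raw")) {
  scales <- match.arg(scales, c("log", "raw"), several.ok = TRUE)
  idcols <- c("obs_id", "series_id", "year")
  if (is.null(indices)) {
    indices <- setdiff(names(diversity)[vapply(diversity, is.numeric, TRUE)],
                       idcols)
  }
  years_by <- split(diversity$year, diversity$series_id)
  sids <- names(years_by)
  n_out <- length(sids) * length(indices) * length(scales)
  col_series <- col_index <- col_scale <- col_reason <- character(n_out)
  col_n <- integer(n_out)
  col_span <- col_slope <- col_pct <- col_w <- numeric(n_out)
  k <- 0L
  for (idx in indices) {
    vals_by <- split(diversity[[idx]], diversity$series_id)
    for (i in seq_along(sids)) {
      for (sc in scales) {
        fit <- fit_series_trend(
          years_by[[i]], vals_by[[i]], scale = sc,
          offset = if (sc == "log" && idx %in% count_offset_indices) 0.5 else 0
        )
        k <- k + 1L
        col_series[k] <- sids[i]; col_index[k] <- idx; col_scale[k] <- sc
        col_n[k] <- fit$n_obs; col_span[k] <- fit$span
        col_slope[k] <- fit$slope; col_pct[k] <- fit$pct_per_year
        col_w[k] <- fit$weight; col_reason[k] <- fit$reason
      }
    }
  }
  data.frame(
    series_id = col_series, index = col_index, scale = col_scale,
    n_obs = col_n, span = col_span, slope = col_slope,
    pct_per_year = col_pct, weight = col_w, reason = col_reason,
    stringsAsFactors = FALSE
  )
}
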