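#' Decadal gamma-diversity trends with sample-matched decade pairing
#'
#' Pooled (gamma) richness comparisons are biased by unequal plot numbers
#' across periods, so each comparison is restricted to the plots observed
#' in both decades of a pair. Decades are fixed calendar decades
#' (1900-1909, 1910-1919, ...). For every ordered decade pair d1 < d2 the
#' qualifying plots contribute their first observation in d1 and their
#' last observation in d2; gamma is the count of unique taxa pooled over
#' the selected observations, and the trend is the gamma difference divided
#' by the pair's temporal distance in decades. Pairs with no qualifying
#' plot are skipped.
#'
#' @param community long community table (columns `obs_id`, `year`,
#'   `taxon`, and the pairing key), typically one habitat x trajectory
#'   group of `dataset$community`.
#' @param plot_key column identifying a plot (default `"plot_id"`, falling
#'   back to `"series_id"` for N-to-N designs without stable plot ids).
#' @return data frame: `decade1`, `decade2`, `n_plots`, `gamma1`, `gamma2`,
#'   `trend` (taxa per decade).
#' @export
decadal_gamma_trends <- function(community, plot_key = "plot_id") {
  if (!plot_key %in% names(community)) plot_key <- "series_id"
  comm <- community[!is.na(community$year), , drop = FALSE]
  comm$.decade <- (comm$year %/% 10L) * 10L
  comm$.plot <- comm[[plot_key]]

  obs <- unique(comm[, c("obs_id", ".plot", "year", ".decade")])
  decades <- sort(unique(obs$.decade))
  if (length(decades) < 2L) {
    return(data.frame(decade1 = integer(0), decade2 = integer(0),
                      n_plots = integer(0), gamma1 = integer(0),
                      gamma2 = integer(0), trend = numeric(0)))
  }
  taxa_by_obs <- split(comm$taxon, comm$obs_id)
  out <- list()
  for (i in seq_len(length(decades) - 1L)) {
    for (j in seq.int(i + 1L, length(decades))) {
      d1 <- decades[i]; d2 <- decades[j]
      o1 <- obs[obs$.decade == d1, , drop = FALSE]
      o2 <- obs[obs$.decade == d2, , drop = FALSE]
      plots <- intersect(o1$.plot, o2$.plot)
      if (!length(plots)) next
      first_in <- vapply(plots, function(p) {
        po <- o1[o1$.plot == p, , drop = FALSE]
        po$obs_id[order(po$year, po$obs_id)][1L]
      }, "")
      last_in <- vapply(plots, function(p) {
        po <- o2[o2$.plot == p, , drop = FALSE]
        po$obs_id[order(po$year, po$obs_id)][nrow(po)]
      }, "")
      g1 <- length(unique(unlist(taxa_by_obs[first_in], use.names = FALSE)))
      g2 <- length(unique(unlist(taxa_by_obs[last_in], use.names = FALSE)))
      out[[length(out) + 1L]] <- data.frame(
        decade1 = d1, decade2 = d2, n_plots = length(plots),
        gamma1 = g1, gamma2 = g2,
        trend = (g2 - g1) / ((d2 - d1) / 10), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(decade1 = integer(0), decade2 = integer(0),
                      n_plots = integer(0), gamma1 = integer(0),
                      gamma2 = integer(0), trend = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test decadal gamma-diversity trends of one group
#'
#' Two-sided one-sample t-test of the mean decadal trend against zero, and
#' an exact two-sided binomial sign test of positive versus negative trends
#' (zero trends excluded). Degenerate cases follow fixed conventions: with
#' fewer than two trends or all trends zero the t-test is skipped; zero
#' variance around a non-zero mean is reported as p = 1e-15; with no
#' non-zero trend the binomial test is skipped.
#'
#' @param trends `trend` column (or output) of [decadal_gamma_trends()].
#' @return one-row data frame: `n_trends`, `mean_trend`, `t_p`,
#'   `n_positive`, `n_negative`, `binomial_p`, `t_skipped_reason`,
#'   `binom_skipped_reason`.
#' @export
test_gamma_trends <- function(trends) {
  if (is.data.frame(trends)) trends <- trends$trend
  trends <- trends[!is.na(trends)]
  n <- length(trends)
  n_pos <- sum(trends > 0); n_neg <- sum(trends < 0)
  res <- data.frame(
    n_trends = n, mean_trend = if (n) mean(trends) else NA_real_,
    t_p = NA_real_, n_positive = n_pos, n_negative = n_neg,
    binomial_p = NA_real_, t_skipped_reason = NA_character_,
    binom_skipped_reason = NA_character_, stringsAsFactors = FALSE)
  if (n < 2L) {
    res$t_skipped_reason <- "fewer_than_2_trends"
  } else if (sd(trends) == 0) {
    if (mean(trends) == 0) {
      res$t_skipped_reason <- "all_trends_zero"
    } else {
      res$t_p <- 1e-15   # degenerate: identical non-zero trends
    }
  } else {
    res$t_p <- t.test(trends)$p.value
  }
  if (n_pos + n_neg == 0L) {
    res$binom_skipped_reason <- "no_nonzero_trends"
  } else {
    res$binomial_p <- binom.test(n_pos, n_pos + n_neg, 0.5)$p.value
  }
  res
}

#' Gamma-diversity trend tests per habitat x trajectory group
#'
#' Convenience wrapper running [decadal_gamma_trends()] and
#' [test_gamma_trends()] for every combination of habitat level-1 code and
#' trajectory category.
#'
#' @param dataset an `rsv_dataset`.
#' @param trajectories output of [assign_trajectories()].
#' @param plot_key see [decadal_gamma_trends()].
#' @return list with `trends` (all decade pairs, with group labels) and
#'   `tests` (one row per group).
#' @export
gamma_trends_by_group <- function(dataset, trajectories,
                                  plot_key = "plot_id") {
  comm <- dataset$community
  l1 <- tapply(comm$eunis_l1, comm$series_id, function(v) v[!is.na(v)][1L])
  comm$.group_l1 <- as.character(l1[comm$series_id])
  comm$.group_traj <- trajectories$trajectory[
    match(comm$series_id, trajectories$series_id)]
  comm <- comm[!is.na(comm$.group_l1) & !is.na(comm$.group_traj), ,
               drop = FALSE]
  key <- paste(comm$.group_l1, comm$.group_traj, sep = " / ")
  all_tr <- list(); tests <- list()
  for (kk in sort(unique(key))) {
    g <- comm[key == kk, , drop = FALSE]
    tr <- decadal_gamma_trends(g, plot_key)
    if (nrow(tr)) {
      tr$group <- kk
      all_tr[[kk]] <- tr
    }
    tst <- test_gamma_trends(tr)
    tst$group <- kk
    tests[[kk]] <- tst
  }
  list(
    trends = if (length(all_tr)) do.call(rbind, all_tr) else NULL,
    tests = do.call(rbind, tests)
  )
}
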