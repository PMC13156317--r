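#' Multiple-site Simpson dissimilarity
#'
#' Multi-site turnover component of beta diversity, independent of richness
#' differences and nestedness: with \eqn{S_i} the richness of site i,
#' \eqn{S_T} the pooled richness, and \eqn{b_{ij} = |site_i \setminus site_j|},
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j} \min(b_{ij}, b_{ji})}
#'   {\left(\sum_i S_i - S_T\right) + \sum_{i<j} \min(b_{ij}, b_{ji})}.}
#' Returns 0 when every pairwise minimum turnover term is 0 (nested or
#' identical communities).
#'
#' @param communities list (length >= 2) of non-empty character vectors of
#'   taxa (species sets).
#' @return dissimilarity in \[0, 1\].
#' @examples
#' multiple_simpson(list(c("A", "B"), c("B", "C"), c("A", "C"))) # 0.5
#' @export
multiple_simpson <- function(communities) {
  if (!is.list(communities) || length(communities) < 2L) {
    stop("need at least two communities")
  }
  sets <- lapply(communities, unique)
  if (any(lengths(sets) == 0L)) stop("communities must be non-empty")
  k <- length(sets)
  pool <- unique(unlist(sets))
  # presence matrix for fast pairwise intersections
  pm <- vapply(sets, function(s) pool %in% s, logical(length(pool)))
  pm <- matrix(pm, nrow = length(pool))
  sizes <- colSums(pm)
  shared <- crossprod(pm)                 # a_ij = |s_i intersect s_j|
  min_b <- outer(sizes, sizes, pmin) - shared
  sum_min <- sum(min_b[upper.tri(min_b)])
  if (sum_min == 0) return(0)
  denom <- (sum(sizes) - length(pool)) + sum_min
  sum_min / denom
}

#' Estimate species niche widths from co-occurrence
#'
#' Co-occurrence proxy for habitat specialization: generalists co-occur with
#' more heterogeneous species sets than specialists. For every species with
#' at least `min_occ` plot occurrences spread over at least `n_plots`
#' distinct time series, `n_reps` replicates each draw `n_plots` occurrence
#' observations (at most one per time series) and compute the multiple-site
#' Simpson dissimilarity across their full communities; the niche width is
#' the mean over replicates. Species below the occurrence threshold, or with
#' too few distinct series, stay unscored with the reason recorded.
#'
#' @param dataset an `rsv_dataset` (post-filtering).
#' @param n_plots observations per replicate (default 20).
#' @param n_reps replicates per species (default 100).
#' @param min_occ minimum plot occurrences (default 50).
#' @param seed integer seed for the replicate sampling.
#' @return data frame (`taxon`, `n_occurrences`, `n_series`, `niche_width`,
#'   `n_reps`, `reason`) with class `niche_width_table`.
#' @export
estimate_niche_widths <- function(dataset, n_plots = 20L, n_reps = 100L,
                                  min_occ = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comm <- dataset$community
  occ <- unique(comm[, c("obs_id", "series_id", "taxon")])
  obs_species <- split(occ$taxon, occ$obs_id)

  taxa <- sort(unique(occ$taxon))
  res <- data.frame(taxon = taxa, n_occurrences = 0L, n_series = 0L,
                    niche_width = NA_real_, n_reps = 0L,
                    reason = NA_character_, stringsAsFactors = FALSE)
  occ_by_taxon <- split(occ[, c("obs_id", "series_id")], occ$taxon)

  for (i in seq_along(taxa)) {
    o <- occ_by_taxon[[taxa[i]]]
    res$n_occurrences[i] <- nrow(o)
    res$n_series[i] <- length(unique(o$series_id))
    if (nrow(o) < min_occ) {
      res$reason[i] <- "below_min_occurrences"
      next
    }
    if (res$n_series[i] < n_plots) {
      res$reason[i] <- "too_few_distinct_series"
      next
    }
    by_series <- split(o$obs_id, o$series_id)
    widths <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      sel_series <- sample(names(by_series), n_plots)
      sel_obs <- vapply(by_series[sel_series], function(v) {
        if (length(v) == 1L) v else sample(v, 1L)
      }, "")
      widths[r] <- multiple_simpson(obs_species[sel_obs])
    }
    res$niche_width[i] <- mean(widths)
    res$n_reps[i] <- n_reps
  }
  class(res) <- c("niche_width_table", "data.frame")
  res
}

#' Classify species into habitat specialists and generalists
#'
#' The lowest decile of scored niche widths become specialists, the highest
#' decile generalists, the rest intermediate; unscored species are labelled
#' `"unscored"`. Decile membership counts are `floor(q * n_scored)` per
#' tail; ties are broken by taxon name so the classification is
#' deterministic and the classes always partition the species.
#'
#' @param table output of [estimate_niche_widths()].
#' @param lower_q,upper_q tail fractions (default 0.10 each).
#' @return the table with a `niche_class` column added.
#' @export
classify_niche_categories <- function(table, lower_q = 0.10, upper_q = 0.10) {
  stopifnot(is.data.frame(table), "niche_width" %in% names(table))
  tb <- table
  tb$niche_class <- "unscored"
  scored <- which(!is.na(tb$niche_width))
  ns <- length(scored)
  if (ns >= 10L) {
    ord <- scored[order(tb$niche_width[scored], tb$taxon[scored])]
    n_lo <- floor(lower_q * ns)
    n_hi <- floor(upper_q * ns)
    tb$niche_class[ord] <- "intermediate"
    if (n_lo > 0L) tb$niche_class[ord[seq_len(n_lo)]] <- "specialist"
    if (n_hi > 0L) tb$niche_class[ord[seq.int(ns - n_hi + 1L, ns)]] <- "generalist"
  } else if (ns > 0L) {
    tb$niche_class[scored] <- "intermediate"
  }
  tb
}
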