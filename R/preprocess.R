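#' Combine per-layer covers of one taxon into a single cover value
#'
#' Species recorded in several vegetation layers of the same plot overlap
#' at random under an independence assumption, so the combined horizontal
#' projection is \eqn{100 (1 - \prod_l (1 - c_l/100))}. The same formula,
#' applied across taxa, yields total vegetation cover.
#'
#' @param covers numeric vector of percent covers in \[0, 100\] (one per layer).
#' @return a single percent cover in \[0, 100\].
#' @examples
#' combine_layer_cover(c(50, 50)) # 75
#' @export
combine_layer_cover <- function(covers) {
  covers <- covers[!is.na(covers)]
  if (length(covers) == 0L) return(0)
  if (any(covers < 0 | covers > 100)) {
    stop("cover values must lie in [0, 100]")
  }
  100 * (1 - prod(1 - covers / 100))
}

#' Total vegetation cover of a plot observation
#'
#' Overlap-corrected proportion of plot area covered by vegetation: the
#' independence combination of the (already layer-combined) per-taxon covers.
#'
#' @param covers numeric vector of per-taxon percent covers (layer-combined).
#' @return percent of plot area covered, 0 for an empty observation.
#' @export
total_vegetation_cover <- function(covers) {
  combine_layer_cover(covers)
}

#' Apply the standard cleaning rules to a resurvey dataset
#'
#' Removes (1) experimentally manipulated plot observations, (2) series whose
#' observations carry no cover information (presence/absence only), and
#' (3) series whose plot area changed by a factor of more than two between
#' any two observations. A series where plot size is recorded for some but
#' not all observations is retained and flagged; the area-ratio rule is
#' skipped for it with a warning.
#'
#' The function is idempotent: filtering an already-filtered dataset removes
#' nothing further.
#'
#' @param dataset an `rsv_dataset` (see [load_dataset()]).
#' @return the filtered dataset, with a `filter_report` attribute: a data
#'   frame of per-rule removal counts (series and observations).
#' @export
filter_dataset <- function(dataset) {
  comm <- dataset$community
  n_series_in <- length(unique(comm$series_id))
  n_obs_in <- length(unique(comm$obs_id))

  report <- data.frame(
    rule = c("manipulated", "presence_absence_only", "plot_size_ratio_gt2"),
    series_removed = 0L, obs_removed = 0L,
    stringsAsFactors = FALSE
  )

  # rule 1: manipulated observations
  manip_obs <- unique(comm$obs_id[comm$manipulated %in% TRUE])
  comm1 <- comm[!comm$obs_id %in% manip_obs, , drop = FALSE]
  report$obs_removed[1] <- length(manip_obs)
  report$series_removed[1] <-
    n_series_in - length(unique(comm1$series_id))

  # rule 2: series with no cover values at all
  cover_by_series <- tapply(!is.na(comm1$cover), comm1$series_id, any)
  pa_series <- names(cover_by_series)[!cover_by_series]
  comm2 <- comm1[!comm1$series_id %in% pa_series, , drop = FALSE]
  report$series_removed[2] <- length(pa_series)
  report$obs_removed[2] <-
    length(unique(comm1$obs_id)) - length(unique(comm2$obs_id))

  # rule 3: plot-size ratio strictly greater than two
  obs_tab <- unique(comm2[, c("series_id", "obs_id", "plot_size")])
  ratio_bad <- partial <- character(0)
  for (sid in unique(obs_tab$series_id)) {
    sizes <- obs_tab$plot_size[obs_tab$series_id == sid]
    if (all(is.na(sizes))) next
    if (anyNA(sizes)) { partial <- c(partial, sid); next }
    if (max(sizes) / min(sizes) > 2) ratio_bad <- c(ratio_bad, sid)
  }
  if (length(partial)) {
    warning(sprintf(
      "plot size missing on some observations of %d series; area-ratio rule skipped for: %s",
      length(partial), paste(partial, collapse = ", ")
    ))
  }
  comm3 <- comm2[!comm2$series_id %in% ratio_bad, , drop = FALSE]
  report$series_removed[3] <- length(ratio_bad)
  report$obs_removed[3] <-
    length(unique(comm2$obs_id)) - length(unique(comm3$obs_id))

  out <- dataset
  out$community <- comm3
  attr(out, "filter_report") <- report
  attr(report, "input_counts") <- c(series = n_series_in, observations = n_obs_in)
  attr(out, "filter_report") <- report
  out
}

#' Flag candidate taxonomic name mismatches within resurvey sites
#'
#' Searches for systematic name drift: a taxon lost while a congeneric taxon
#' is gained between two consecutive observations of the same plot. A
#' (lost, gained) pair is flagged for a site when the site holds at least
#' `min_plots` plots and the pair occurs in strictly more than
#' `min_fraction` of them. Flags are advisory; no renaming is performed.
#'
#' @param dataset an `rsv_dataset`.
#' @param site_key name of the community-table column that groups plots into
#'   sites/projects; defaults to `"series_id"` (every series its own site)
#'   when no dedicated site column exists.
#' @param plot_key column identifying a plot within a site; consecutive
#'   observations are ordered by year within plot.
#' @param min_plots minimum number of plots a site must hold.
#' @param min_fraction exclusive lower bound on the affected-plot fraction.
#' @return data frame with columns `site`, `lost_taxon`, `gained_taxon`,
#'   `n_plots_affected`, `n_plots_site`, `fraction_affected`.
#' @export
flag_name_mismatches <- function(dataset, site_key = "series_id",
                                 plot_key = "plot_id",
                                 min_plots = 5L, min_fraction = 0.40) {
  comm <- dataset$community
  if (!site_key %in% names(comm)) stop("site_key column not found: ", site_key)
  if (!plot_key %in% names(comm)) plot_key <- "series_id"
  genus <- function(x) vapply(strsplit(x, "[ _]"), `[`, "", 1L)

  flags <- list()
  for (site in unique(comm[[site_key]])) {
    sc <- comm[comm[[site_key]] == site, , drop = FALSE]
    plots <- unique(sc[[plot_key]])
    if (length(plots) < min_plots) next
    # pair -> set of plots in which it occurs
    pair_plots <- new.env(parent = emptyenv())
    for (pl in plots) {
      pc <- sc[sc[[plot_key]] == pl, , drop = FALSE]
      yrs <- sort(unique(pc$year))
      if (length(yrs) < 2L) next
      seen <- character(0)
      for (k in seq_len(length(yrs) - 1L)) {
        t1 <- unique(pc$taxon[pc$year == yrs[k]])
        t2 <- unique(pc$taxon[pc$year == yrs[k + 1L]])
        lost <- setdiff(t1, t2); gained <- setdiff(t2, t1)
        if (!length(lost) || !length(gained)) next
        for (lt in lost) for (gt in gained) {
          if (genus(lt) != genus(gt)) next
          # congeners must still be present at both dates
          key <- paste(lt, gt, sep = "\r")
          if (key %in% seen) next
          seen <- c(seen, key)
          cur <- if (is.null(pair_plots[[key]])) character(0) else pair_plots[[key]]
          pair_plots[[key]] <- union(cur, pl)
        }
      }
    }
    for (key in ls(pair_plots)) {
      n_aff <- length(pair_plots[[key]])
      frac <- n_aff / length(plots)
      if (frac > min_fraction) {
        pr <- strsplit(key, "\r", fixed = TRUE)[[1]]
        flags[[length(flags) + 1L]] <- data.frame(
          site = site, lost_taxon = pr[1], gained_taxon = pr[2],
          n_plots_affected = n_aff, n_plots_site = length(plots),
          fraction_affected = frac, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(flags)) {
    return(data.frame(
      site = character(0), lost_taxon = character(0),
      gained_taxon = character(0), n_plots_affected = integer(0),
      n_plots_site = integer(0), fraction_affected = numeric(0)
    ))
  }
  do.call(rbind, flags)
}

#' Log-transform, standardize, and decorrelate a trait matrix
#'
#' Trait values are log-transformed (non-positive values become missing with
#' a warning), then each column is z-scored over its non-missing entries.
#' Collinearity is reduced either by restricting to `keep_list` or by greedy
#' pruning: while any retained pair has Pearson |r| above `r_cutoff`, the
#' member of the worst pair with the larger mean |r| against all other
#' retained traits is dropped (ties broken lexicographically, dropping the
#' later name). Zero-variance columns are dropped with a warning.
#'
#' @param traits numeric matrix, taxa in rows (rownames), traits in columns.
#' @param r_cutoff pairwise Pearson correlation threshold (default 0.6).
#' @param keep_list optional character vector of trait names to retain
#'   verbatim (bypasses the greedy filter).
#' @return standardized trait matrix (attribute `standardized = TRUE`),
#'   with a `dropped` attribute naming removed columns.
#' @export
prepare_traits <- function(traits, r_cutoff = 0.6, keep_list = NULL) {
  stopifnot(is.matrix(traits), !is.null(colnames(traits)))
  x <- traits
  if (any(x <= 0, na.rm = TRUE)) {
    warning("non-positive trait values set to missing before log transform")
    x[x <= 0] <- NA
  }
  x <- log(x)
  dropped <- character(0)

  zvar <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2L || sd(v) == 0
  })
  if (any(zvar)) {
    warning("dropping zero-variance trait(s): ",
            paste(colnames(x)[zvar], collapse = ", "))
    dropped <- colnames(x)[zvar]
    x <- x[, !zvar, drop = FALSE]
  }
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  # rescale so the column *variance* (not just sd of scale()) is exactly 1
  x <- apply(x, 2, function(v) {
    m <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
    (v - m) / s
  })
  rownames(x) <- rownames(traits)

  if (!is.null(keep_list)) {
    missing_tr <- setdiff(keep_list, colnames(x))
    if (length(missing_tr)) stop("keep_list traits absent: ",
                                 paste(missing_tr, collapse = ", "))
    dropped <- c(dropped, setdiff(colnames(x), keep_list))
    x <- x[, keep_list, drop = FALSE]
  } else {
    repeat {
      if (ncol(x) < 2L) break
      r <- abs(cor(x, use = "pairwise.complete.obs"))
      diag(r) <- 0
      if (max(r, na.rm = TRUE) <= r_cutoff) break
      worst <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      cand <- colnames(x)[worst]
      mean_r <- vapply(cand, function(nm) {
        mean(r[nm, setdiff(colnames(x), nm)], na.rm = TRUE)
      }, 0)
      drop_nm <- if (abs(diff(mean_r)) > 1e-12) {
        cand[which.max(mean_r)]
      } else {
        sort(cand)[2L]   # lexicographic tie-break: drop the later name
      }
      dropped <- c(dropped, drop_nm)
      x <- x[, setdiff(colnames(x), drop_nm), drop = FALSE]
    }
  }
  attr(x, "standardized") <- TRUE
  attr(x, "dropped") <- dropped
  x
}
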