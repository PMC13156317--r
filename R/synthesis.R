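#' Weighted mean trend with Wald confidence interval
#'
#' Intercept of a weighted least squares fit with analytic (importance)
#' weights: the estimate is \eqn{\sum w_i x_i / \sum w_i} with standard
#' error \eqn{\sqrt{\sum w_i (x_i - \bar x_w)^2 / ((n - p) \sum w_i)}}.
#' With covariates supplied they enter as fixed effects centred at their
#' weighted means, so the intercept remains the adjusted average trend.
#'
#' @param x per-series trend values (e.g. annual percentage changes).
#' @param weights positive weights, conventionally `log(n_obs)`.
#' @param covariates optional data frame of numeric covariates (e.g.
#'   resurvey design as 0/1, relative plot-size change).
#' @param label subgroup label stored in the output (default `"all"`).
#' @param index index name stored in the output.
#' @return one-row data frame: `index`, `subgroup`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `n_series`, `significant`.
#' @export
weighted_mean_trend <- function(x, weights, covariates = NULL,
                                label = "all", index = NA_character_) {
  keep <- !is.na(x) & !is.na(weights)
  x <- x[keep]; w <- weights[keep]
  n <- length(x)
  if (n < 2L) stop("need at least two trend records")
  if (any(w <= 0)) stop("weights must be positive")
  if (is.null(covariates)) {
    est <- sum(w * x) / sum(w)
    se <- sqrt(sum(w * (x - est)^2) / ((n - 1) * sum(w)))
  } else {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    cv[] <- lapply(cv, function(v) {
      v <- as.numeric(v)
      v - weighted.mean(v, w)
    })
    fit <- suppressWarnings(
      lm(x ~ ., data = cbind(data.frame(x = x), cv), weights = w))
    est <- unname(coef(fit)[1L])
    se <- unname(sqrt(diag(vcov(fit)))[1L])
  }
  pooled_trend(index, label, est, se, n)
}

pooled_trend <- function(index, subgroup, estimate, se, n_series) {
  ci_lo <- estimate - 1.96 * se
  ci_hi <- estimate + 1.96 * se
  data.frame(index = index, subgroup = subgroup, estimate = estimate,
             se = se, ci_lo = ci_lo, ci_hi = ci_hi, n_series = n_series,
             significant = (ci_lo > 0 | ci_hi < 0),
             stringsAsFactors = FALSE)
}

#' Habitat-balanced mean trend
#'
#' Every EUNIS level-3 habitat type receives equal total weight: series of
#' habitat h get weight 1/n_h, after dropping habitats represented by fewer
#' than `min_per_habitat` series. Optionally the balanced weight is
#' multiplied by the ln(n_obs) weight.
#'
#' @param x per-series trend values.
#' @param habitat_l3 EUNIS level-3 label per series.
#' @param obs_weights optional ln(n_obs) weights, used only when
#'   `combine_obs_weight = TRUE`.
#' @param min_per_habitat exclusion threshold (default 10 series).
#' @param combine_obs_weight multiply balanced and observation-count
#'   weights (default `FALSE`).
#' @param index index name stored in the output.
#' @return one-row pooled-trend data frame (see [weighted_mean_trend()]).
#' @export
balanced_mean_trend <- function(x, habitat_l3, obs_weights = NULL,
                                min_per_habitat = 10L,
                                combine_obs_weight = FALSE,
                                index = NA_character_) {
  keep <- !is.na(x) & !is.na(habitat_l3)
  x <- x[keep]; h <- habitat_l3[keep]
  if (!is.null(obs_weights)) obs_weights <- obs_weights[keep]
  tab <- table(h)
  ok_h <- names(tab)[tab >= min_per_habitat]
  if (!length(ok_h)) stop("no habitat reaches min_per_habitat series")
  sel <- h %in% ok_h
  x <- x[sel]; h <- h[sel]
  w <- 1 / as.numeric(table(h)[h])
  if (combine_obs_weight) {
    if (is.null(obs_weights)) stop("obs_weights required when combining")
    w <- w * obs_weights[sel]
  }
  weighted_mean_trend(x, w, label = "balanced", index = index)
}

#' Pooled trends per habitat x trajectory subgroup
#'
#' Weighted mean trend (ln n_obs weights, Wald CI) for every combination of
#' the grouping labels; cells with fewer than `min_n` series are emitted
#' with `eligible = FALSE` (estimates still reported when n >= 2), empty
#' cells are absent.
#'
#' @param trends data frame with at least `pct_per_year` and `weight`.
#' @param by data frame of grouping labels aligned with `trends` rows
#'   (e.g. habitat level 1 and trajectory).
#' @param min_n eligibility threshold (default 10).
#' @return pooled-trend data frame with one row per non-empty cell and an
#'   `eligible` column.
#' @export
subgroup_trends <- function(trends, by, min_n = 10L) {
  by <- as.data.frame(by, stringsAsFactors = FALSE)
  keep <- !is.na(trends$pct_per_year) & stats::complete.cases(by)
  tr <- trends[keep, , drop = FALSE]
  by <- by[keep, , drop = FALSE]
  key <- do.call(paste, c(by, sep = " / "))
  out <- lapply(unique(key), function(kk) {
    sel <- key == kk
    n <- sum(sel)
    if (n >= 2L) {
      row <- weighted_mean_trend(tr$pct_per_year[sel], tr$weight[sel],
                                 label = kk, index = tr$index[sel][1L])
    } else {
      row <- pooled_trend(tr$index[sel][1L], kk,
                          mean(tr$pct_per_year[sel]), NA_real_, n)
      row$significant <- NA
    }
    row$eligible <- n >= min_n
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sample weighted Welch t-test
#'
#' Weights are rescaled within each group to sum to the group size
#' (frequency-style), then the usual Welch statistic is formed from the
#' weighted means and variances with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param x1,x2 samples.
#' @param w1,w2 positive weights.
#' @return list with `t`, `df`, `p_value`, `mean1`, `mean2`.
#' @export
weighted_t_test <- function(x1, w1, x2, w2) {
  stopifnot(length(x1) == length(w1), length(x2) == length(w2))
  f <- function(x, w) {
    n <- length(x)
    w <- w * n / sum(w)
    m <- sum(w * x) / n
    v <- sum(w * (x - m)^2) / (n - 1)
    list(n = n, m = m, v = v)
  }
  a <- f(x1, w1); b <- f(x2, w2)
  se2 <- a$v / a$n + b$v / b$n
  t_stat <- (a$m - b$m) / sqrt(se2)
  df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p_value = p, mean1 = a$m, mean2 = b$m)
}

#' Compare diversity trends before and after a split year
#'
#' Observations are split into a pre and a post period (also within a
#' series; the split year itself starts the post period), per-series trends
#' are refitted within each period, and the two groups of annual percentage
#' changes are compared per index with the weighted Welch t-test (ln n_obs
#' weights). Following common practice the comparison is restricted to
#' habitat level-1 classes with dense coverage in both periods (default
#' grasslands R, shrublands S, forests T); pass `habitats = NULL` to keep
#' all series.
#'
#' @param dataset an `rsv_dataset`.
#' @param diversity output of [compute_diversity()].
#' @param split_year split point (default 2000).
#' @param indices index columns to compare (default: all fitted).
#' @param habitats level-1 codes retained, or `NULL`.
#' @return data frame per index: period means, t, df, p-value, group sizes;
#'   indices where either period has fewer than two eligible series are
#'   reported with `NA` statistics.
#' @export
compare_periods <- function(dataset, diversity, split_year = 2000L,
                            indices = NULL, habitats = c("R", "S", "T")) {
  comm <- dataset$community
  if (!is.null(habitats)) {
    l1 <- tapply(comm$eunis_l1, comm$series_id, function(v) v[!is.na(v)][1L])
    keep_series <- names(l1)[l1 %in% habitats]
    diversity <- diversity[diversity$series_id %in% keep_series, , drop = FALSE]
  }
  pre <- diversity[diversity$year < split_year, , drop = FALSE]
  post <- diversity[diversity$year >= split_year, , drop = FALSE]
  if (is.null(indices)) {
    indices <- setdiff(names(diversity)[vapply(diversity, is.numeric, TRUE)],
                       c("obs_id", "series_id", "year"))
  }
  out <- lapply(indices, function(idx) {
    res <- data.frame(index = idx, mean_pre = NA_real_, mean_post = NA_real_,
                      t = NA_real_, df = NA_real_, p_value = NA_real_,
                      n_pre = 0L, n_post = 0L, stringsAsFactors = FALSE)
    g <- lapply(list(pre, post), function(dv) {
      if (!nrow(dv)) return(NULL)
      tr <- compute_all_trends(dv, indices = idx, scales = "log")
      tr[is.na(tr$reason) & !is.na(tr$pct_per_year), , drop = FALSE]
    })
    res$n_pre <- if (is.null(g[[1]])) 0L else nrow(g[[1]])
    res$n_post <- if (is.null(g[[2]])) 0L else nrow(g[[2]])
    if (res$n_pre >= 2L && res$n_post >= 2L) {
      tt <- weighted_t_test(g[[1]]$pct_per_year, g[[1]]$weight,
                            g[[2]]$pct_per_year, g[[2]]$weight)
      res$mean_pre <- tt$mean1; res$mean_post <- tt$mean2
      res$t <- tt$t; res$df <- tt$df; res$p_value <- tt$p_value
    }
    res
  })
  do.call(rbind, out)
}

# R^2 of an ordinary least squares projection on an arbitrary design
.r2 <- function(y, xmat) {
  if (is.null(xmat) || ncol(xmat) == 0L) return(0)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xmat), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' General dominance shares of predictor blocks
#'
#' Decomposes a linear model's R^2 into per-block shares by averaging the
#' incremental R^2 of each block over all admissible entry orders
#' (Shapley-style). An entry in `requires` constrains a block (typically an
#' interaction) to enter only after the named blocks (its main effects);
#' averaging over the correspondingly restricted orderings keeps the
#' identity sum(shares) = R^2 of the full model exact.
#'
#' @param y response vector.
#' @param blocks named list of design matrices (no intercept column).
#' @param requires named list: block name -> character vector of blocks
#'   that must precede it.
#' @return list with `shares` (named numeric) and `r2_full`.
#' @export
dominance_shares <- function(y, blocks, requires = list()) {
  nm <- names(blocks)
  stopifnot(length(nm) == length(blocks), !is.null(nm))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  admissible <- Filter(function(ord) {
    all(vapply(seq_along(ord), function(i) {
      req <- requires[[ord[i]]]
      is.null(req) || all(req %in% ord[seq_len(i - 1L)])
    }, TRUE))
  }, perms(nm))
  if (!length(admissible)) stop("no admissible ordering of blocks")

  r2_cache <- new.env(parent = emptyenv())
  r2_of <- function(set) {
    key <- paste0("k:", paste(sort(set), collapse = "|"))
    if (is.null(r2_cache[[key]])) {
      xm <- if (length(set)) do.call(cbind, blocks[set]) else NULL
      r2_cache[[key]] <- .r2(y, xm)
    }
    r2_cache[[key]]
  }
  shares <- setNames(numeric(length(nm)), nm)
  for (ord in admissible) {
    prev <- character(0)
    for (b in ord) {
      shares[b] <- shares[b] + (r2_of(c(prev, b)) - r2_of(prev))
      prev <- c(prev, b)
    }
  }
  shares <- shares / length(admissible)
  list(shares = shares, r2_full = r2_of(nm))
}

#' Dominance analysis of diversity-trend variation within one habitat
#'
#' Partitions the variance of per-series annual percentage changes among
#' four predictor blocks: EUNIS level-3 habitat type, habitat-change
#' trajectory (stable / succession / disturbance), their interaction, and
#' the year of the last observation. Eligibility requires at least two
#' level-3 habitats, each holding at least two trajectories with at least
#' `min_cell` series each (2 x 2 x 10 = 40 series at the defaults); the
#' analysis runs on the series of qualifying cells only. The full-model
#' p-value is the analysis-of-variance F-test against the intercept-only
#' model.
#'
#' @param trends data frame, one row per series, with columns
#'   `pct_per_year`, `habitat_l3`, `trajectory`, `last_year`.
#' @param min_cell minimum series per (habitat, trajectory) cell
#'   (default 10).
#' @return list with `eligible`, and when eligible: `shares` (named:
#'   `habitat_l3`, `trajectory`, `interaction`, `last_year`), `r2_full`,
#'   `p_value`, `n_series`.
#' @export
dominance_analysis <- function(trends, min_cell = 10L) {
  tr <- trends[trends$trajectory %in% c("stable", "succession", "disturbance") &
                 !is.na(trends$pct_per_year) & !is.na(trends$habitat_l3) &
                 !is.na(trends$last_year), , drop = FALSE]
  if (!nrow(tr)) return(list(eligible = FALSE, reason = "no_usable_series"))
  cell <- table(tr$habitat_l3, tr$trajectory)
  good_cells <- cell >= min_cell
  habs_ok <- rownames(cell)[rowSums(good_cells) >= 2L]
  if (length(habs_ok) < 2L) {
    return(list(eligible = FALSE, reason = "insufficient_replication"))
  }
  keep <- tr$habitat_l3 %in% habs_ok
  keep <- keep & good_cells[cbind(match(tr$habitat_l3, rownames(cell)),
                                  match(tr$trajectory, colnames(cell)))]
  tr <- tr[keep, , drop = FALSE]
  tr$habitat_l3 <- factor(tr$habitat_l3)
  tr$trajectory <- factor(tr$trajectory)

  mm <- function(fml) {
    m <- stats::model.matrix(fml, tr)
    m[, setdiff(colnames(m), "(Intercept)"), drop = FALSE]
  }
  blocks <- list(
    habitat_l3 = mm(~habitat_l3),
    trajectory = mm(~trajectory),
    interaction = mm(~habitat_l3:trajectory),
    last_year = matrix(tr$last_year, ncol = 1L,
                       dimnames = list(NULL, "last_year"))
  )
  ds <- dominance_shares(tr$pct_per_year, blocks,
                         requires = list(interaction = c("habitat_l3",
                                                         "trajectory")))
  full <- lm(pct_per_year ~ habitat_l3 * trajectory + last_year, data = tr)
  fs <- summary(full)$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  list(eligible = TRUE, shares = ds$shares, r2_full = ds$r2_full,
       p_value = p, n_series = nrow(tr))
}
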