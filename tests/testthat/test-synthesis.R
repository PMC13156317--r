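test_that("weighted mean trend matches hand-computed values", {
  # weights ln(2) : ln(8) = 1 : 3 on values 0 and 4
  out <- weighted_mean_trend(c(0, 4), log(c(2, 8)))
  expect_equal(out$estimate, 3.0)

  # equal weights reduce to the arithmetic mean and classical SE
  set.seed(61)
  x <- rnorm(25, 1, 2)
  out2 <- weighted_mean_trend(x, rep(2, 25))
  expect_equal(out2$estimate, mean(x))
  expect_equal(out2$se, sd(x) / sqrt(25))
  expect_equal(out2$ci_hi - out2$ci_lo, 2 * 1.96 * out2$se)

  # identical values: degenerate CI at the value
  out3 <- weighted_mean_trend(rep(1.5, 5), log(2:6))
  expect_equal(out3$se, 0)
  expect_equal(out3$ci_lo, 1.5)
  expect_error(weighted_mean_trend(1, 1), "at least two")
  expect_error(weighted_mean_trend(c(1, 2), c(1, -1)), "positive")
})

test_that("design covariates adjust but preserve the intercept meaning", {
  set.seed(62)
  n <- 60
  design <- rep(c(0, 1), n / 2)
  x <- 1 + 0.5 * design + rnorm(n, 0, 0.1)
  w <- log(sample(2:8, n, replace = TRUE))
  plain <- weighted_mean_trend(x, w)
  adj <- weighted_mean_trend(x, w, covariates = data.frame(design = design))
  # with centred covariates the adjusted intercept stays near the
  # weighted mean, and the SE accounts for the design term
  expect_equal(adj$estimate, plain$estimate, tolerance = 0.05)
  expect_equal(adj$n_series, n)
})

test_that("balanced pooling gives each habitat equal impact", {
  x <- c(rep(1, 20), rep(3, 10))
  h <- c(rep("R22", 20), rep("T18", 10))
  out <- balanced_mean_trend(x, h, min_per_habitat = 10)
  expect_equal(out$estimate, 2.0)

  # habitat below the threshold is excluded
  x2 <- c(x, rep(100, 9))
  h2 <- c(h, rep("Q22", 9))
  out2 <- balanced_mean_trend(x2, h2, min_per_habitat = 10)
  expect_equal(out2$estimate, 2.0)

  # single surviving habitat: plain mean of that habitat
  out3 <- balanced_mean_trend(c(rep(2, 12), 9), c(rep("R22", 12), "T18"),
                              min_per_habitat = 10)
  expect_equal(out3$estimate, 2.0)
  expect_error(balanced_mean_trend(c(1, 2), c("a", "b"),
                                   min_per_habitat = 10), "min_per_habitat")

  # replicating one habitat k times leaves the balanced estimate unchanged
  xr <- c(x, rep(1, 40)); hr <- c(h, rep("R22", 40))
  expect_equal(balanced_mean_trend(xr, hr, min_per_habitat = 10)$estimate, 2.0)
})

test_that("subgroup pooling is consistent with the union weighted mean", {
  set.seed(63)
  n <- 80
  trends <- data.frame(
    index = "richness",
    pct_per_year = rnorm(n),
    weight = log(sample(2:9, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  by <- data.frame(l1 = rep(c("R", "T"), each = n / 2),
                   traj = rep(c("stable", "succession"), n / 2))
  cells <- subgroup_trends(trends, by, min_n = 10)
  expect_true(all(cells$n_series >= 1))
  # pooling the two cells of habitat R with their weights reproduces the
  # habitat-level weighted mean
  rsel <- by$l1 == "R"
  direct <- weighted_mean_trend(trends$pct_per_year[rsel],
                                trends$weight[rsel])$estimate
  rcells <- cells[grepl("^R / ", cells$subgroup), ]
  wsum <- vapply(rcells$subgroup, function(s) {
    sel <- paste(by$l1, by$traj, sep = " / ") == s
    sum(trends$weight[sel])
  }, 0)
  pooled <- sum(rcells$estimate * wsum) / sum(wsum)
  expect_equal(pooled, direct)

  # a singleton cell is ineligible
  trends1 <- trends[1:11, ]
  by1 <- data.frame(l1 = c(rep("R", 10), "T"), traj = "stable")
  cells1 <- subgroup_trends(trends1, by1, min_n = 10)
  expect_false(cells1$eligible[cells1$subgroup == "T / stable"])
  expect_true(cells1$eligible[cells1$subgroup == "R / stable"])
})

test_that("weighted t-test reduces to Welch under equal weights", {
  set.seed(64)
  x1 <- rnorm(20, 0); x2 <- rnorm(25, 1)
  ours <- weighted_t_test(x1, rep(3, 20), x2, rep(5, 25))
  ref <- t.test(x1, x2)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p_value, ref$p.value)

  # identical groups: t = 0, p = 1
  same <- weighted_t_test(x1, rep(1, 20), x1, rep(1, 20))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # separated groups: decisive
  sep <- weighted_t_test(rnorm(15, 0, 0.01), rep(1, 15),
                         rnorm(15, 5, 0.01), rep(1, 15))
  expect_lt(sep$p_value, 1e-3)
})

test_that("period comparison refits trends within each period", {
  set.seed(65)
  rows <- list()
  for (i in 1:12) {
    sid <- sprintf("s%02d", i)
    yrs <- c(1980L, 1990L, 2005L, 2015L)
    taxa_n <- c(10, 12, 12, 18) + sample(-1:1, 4, replace = TRUE)
    for (j in 1:4) {
      taxa <- sprintf("Genus%02d sp%02d", 1:taxa_n[j], 1:taxa_n[j])
      rows[[length(rows) + 1L]] <- data.frame(
        obs_id = sprintf("%s_o%d", sid, j), series_id = sid, year = yrs[j],
        plot_size = 25, taxon = taxa, layer = "herb", cover = 30,
        eunis_l1 = "R", eunis_l3 = "R22", design = "permanent",
        manipulated = FALSE, stringsAsFactors = FALSE)
    }
  }
  ds <- rsv_dataset(do.call(rbind, rows))
  div <- compute_diversity(ds, indices = "taxonomic")
  cmp <- compare_periods(ds, div, split_year = 2000, indices = "richness")
  expect_equal(cmp$n_pre, 12)
  expect_equal(cmp$n_post, 12)
  # post-2000 growth is much faster by construction
  expect_gt(cmp$mean_post, cmp$mean_pre)
  expect_false(is.na(cmp$p_value))
  # habitat restriction removes everything when no R/S/T series exist
  ds2 <- ds; ds2$community$eunis_l1 <- "Q"
  cmp2 <- compare_periods(ds2, div, split_year = 2000, indices = "richness")
  expect_equal(cmp2$n_pre + cmp2$n_post, 0)
})

test_that("dominance shares sum to full-model R^2 and respect orthogonality", {
  set.seed(66)
  # orthogonal balanced design: shares equal marginal R^2
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), n / 2)
  y <- 0.8 * x1 + 0.3 * x2 + rnorm(n, 0, 0.5)
  ds <- dominance_shares(y, list(a = cbind(x1), b = cbind(x2)))
  r2_a <- summary(lm(y ~ x1))$r.squared
  r2_b <- summary(lm(y ~ x2))$r.squared
  expect_equal(sum(ds$shares), ds$r2_full, tolerance = 1e-8)
  expect_equal(unname(ds$shares["a"]), r2_a, tolerance = 1e-8)
  expect_equal(unname(ds$shares["b"]), r2_b, tolerance = 1e-8)

  # correlated predictors: identity still exact, order-invariant
  x3 <- x1 + rnorm(n, 0, 0.4)
  y2 <- x1 - 0.5 * x3 + rnorm(n)
  d1 <- dominance_shares(y2, list(a = cbind(x1), c = cbind(x3)))
  d2 <- dominance_shares(y2, list(c = cbind(x3), a = cbind(x1)))
  expect_equal(sum(d1$shares), d1$r2_full, tolerance = 1e-8)
  expect_equal(d1$shares[sort(names(d1$shares))],
               d2$shares[sort(names(d2$shares))])
})

make_dominance_trends <- function(n_per_cell = 12, habitats = c("R22", "R23"),
                                  trajectories = c("stable", "succession"),
                                  seed = 67) {
  set.seed(seed)
  g <- expand.grid(habitat_l3 = habitats, trajectory = trajectories,
                   stringsAsFactors = FALSE)
  rows <- list()
  for (k in seq_len(nrow(g))) {
    eff <- 0.5 * (g$habitat_l3[k] == "R23") - 0.3 * (g$trajectory[k] == "succession")
    rows[[k]] <- data.frame(
      habitat_l3 = g$habitat_l3[k], trajectory = g$trajectory[k],
      last_year = sample(1990:2020, n_per_cell, replace = TRUE),
      pct_per_year = eff + rnorm(n_per_cell, 0, 0.4),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("dominance analysis enforces eligibility and the R^2 identity", {
  tr <- make_dominance_trends()
  out <- dominance_analysis(tr, min_cell = 10)
  expect_true(out$eligible)
  expect_equal(sum(out$shares), out$r2_full, tolerance = 1e-8)
  expect_setequal(names(out$shares),
                  c("habitat_l3", "trajectory", "interaction", "last_year"))
  expect_true(all(out$shares >= -1e-8))
  expect_false(is.na(out$p_value))
  expect_equal(out$n_series, nrow(tr))

  # a single trajectory level is ineligible
  tr1 <- make_dominance_trends(trajectories = "stable")
  expect_false(dominance_analysis(tr1, min_cell = 10)$eligible)
  # under-replicated cells are ineligible
  tr2 <- make_dominance_trends(n_per_cell = 5)
  expect_false(dominance_analysis(tr2, min_cell = 10)$eligible)
})
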