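test_that("layer combination follows the overlap formula", {
  expect_equal(combine_layer_cover(60), 60)
  expect_equal(combine_layer_cover(c(50, 50)), 75)
  expect_equal(combine_layer_cover(c(100, 40)), 100)
  expect_equal(combine_layer_cover(numeric(0)), 0)
  expect_error(combine_layer_cover(c(50, 120)), "\\[0, 100\\]")
})

test_that("layer combination is permutation-invariant, monotone, bounded", {
  set.seed(1)
  for (i in 1:20) {
    x <- runif(sample(2:5, 1), 0, 100)
    expect_equal(combine_layer_cover(x), combine_layer_cover(rev(x)))
    expect_lte(combine_layer_cover(x), 100)
    expect_gte(combine_layer_cover(x), max(x))
    bumped <- x; bumped[1] <- min(100, bumped[1] + 5)
    expect_gte(combine_layer_cover(bumped), combine_layer_cover(x))
  }
})

test_that("total vegetation cover combines taxa with overlap correction", {
  expect_equal(total_vegetation_cover(c(30, 30)), 51)
  expect_equal(total_vegetation_cover(numeric(0)), 0)
  expect_equal(total_vegetation_cover(80), 80)
})

test_that("filter_dataset applies the three cleaning rules", {
  comm <- toy_community()
  # series s2 doubles-plus its plot size (25 -> 100): removed
  comm$plot_size[comm$obs_id %in% c("o4")] <- 100
  ds <- rsv_dataset(comm)
  out <- filter_dataset(ds)
  rep <- attr(out, "filter_report")
  expect_equal(rep$series_removed[rep$rule == "plot_size_ratio_gt2"], 1)
  expect_false("s2" %in% out$community$series_id)

  # ratio exactly 2 is retained (strict threshold)
  comm2 <- toy_community()
  comm2$plot_size[comm2$obs_id == "o4"] <- 50
  out2 <- filter_dataset(rsv_dataset(comm2))
  expect_true("s2" %in% out2$community$series_id)

  # presence/absence-only series removed
  comm3 <- toy_community()
  comm3$cover[comm3$series_id == "s2"] <- NA
  out3 <- filter_dataset(rsv_dataset(comm3))
  expect_false("s2" %in% out3$community$series_id)

  # manipulated observations removed
  comm4 <- toy_community()
  comm4$manipulated[comm4$obs_id == "o1"] <- TRUE
  out4 <- filter_dataset(rsv_dataset(comm4))
  expect_false("o1" %in% out4$community$obs_id)
})

test_that("filter_dataset is idempotent", {
  comm <- toy_community()
  comm$plot_size[comm$obs_id == "o4"] <- 100
  once <- filter_dataset(rsv_dataset(comm))
  twice <- filter_dataset(once)
  expect_identical(once$community, twice$community)
  rep2 <- attr(twice, "filter_report")
  expect_true(all(rep2$series_removed == 0))
})

test_that("name-mismatch flags require >40% of at least five plots", {
  # one site with 6 plots; the Festuca swap occurs in 5 of them (83%)
  mk_site <- function(n_plots, n_affected, site) {
    rows <- list()
    for (p in seq_len(n_plots)) {
      affected <- p <= n_affected
      tax1 <- c("Festuca rubra", "Poa pratensis")
      tax2 <- c(if (affected) "Festuca nigrescens" else "Festuca rubra",
                "Poa pratensis")
      for (ti in 1:2) {
        tax <- list(tax1, tax2)[[ti]]
        rows[[length(rows) + 1L]] <- data.frame(
          obs_id = sprintf("%s_p%d_t%d", site, p, ti),
          series_id = sprintf("%s_p%d", site, p),
          plot_id = sprintf("%s_p%d", site, p),
          site = site, year = c(2000L, 2010L)[ti], plot_size = 25,
          taxon = tax, layer = "herb", cover = 30, eunis_l1 = "R",
          eunis_l3 = "R22", design = "permanent", manipulated = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  ds <- rsv_dataset(mk_site(6, 5, "siteA"))
  ds$community$site <- "siteA"
  flags <- flag_name_mismatches(ds, site_key = "site")
  expect_equal(nrow(flags), 1)
  expect_equal(flags$lost_taxon, "Festuca rubra")
  expect_equal(flags$gained_taxon, "Festuca nigrescens")
  expect_gt(flags$fraction_affected, 0.40)

  # same pattern in a 3-plot site: below the minimum site size
  ds3 <- rsv_dataset(mk_site(3, 3, "siteB"))
  expect_equal(nrow(flag_name_mismatches(ds3, site_key = "site")), 0)

  # exactly 40% affected: strict inequality, not flagged
  ds40 <- rsv_dataset(mk_site(5, 2, "siteC"))
  expect_equal(nrow(flag_name_mismatches(ds40, site_key = "site")), 0)
})

test_that("datasets with unique genera yield no mismatch flags", {
  ds <- toy_dataset()
  expect_equal(nrow(flag_name_mismatches(ds, site_key = "series_id")), 0)
})

test_that("prepare_traits standardizes, prunes, and respects keep_list", {
  set.seed(42)
  n <- 60
  a <- exp(rnorm(n)); b <- exp(rnorm(n)); c3 <- exp(rnorm(n))
  dup <- a * exp(rnorm(n, sd = 0.01))   # near-duplicate of a (r ~ 1)
  m <- cbind(t_a = a, t_b = b, t_c = c3, t_dup = dup)
  rownames(m) <- sprintf("sp%02d", seq_len(n))

  out <- prepare_traits(m)
  expect_true(attr(out, "standardized"))
  for (j in seq_len(ncol(out))) {
    expect_lt(abs(mean(out[, j], na.rm = TRUE)), 1e-8)
    expect_lt(abs(var(out[, j], na.rm = TRUE) - 1), 1e-8)
  }
  # exactly one of the duplicated pair survives
  expect_equal(sum(c("t_a", "t_dup") %in% colnames(out)), 1)
  # independent columns survive the 0.6 cutoff (oracle: direct Pearson)
  r_bc <- abs(cor(log(b), log(c3)))
  expect_lt(r_bc, 0.6)
  expect_true(all(c("t_b", "t_c") %in% colnames(out)))

  kept <- prepare_traits(m, keep_list = c("t_a", "t_b"))
  expect_identical(colnames(kept), c("t_a", "t_b"))

  m2 <- cbind(m, t_const = 1)
  expect_warning(out2 <- prepare_traits(m2), "zero-variance")
  expect_false("t_const" %in% colnames(out2))
})
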