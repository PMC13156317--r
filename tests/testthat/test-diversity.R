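test_that("taxonomic indices follow Shannon and Pielou definitions", {
  tx <- taxonomic_indices(c(a = 25, b = 25, c = 25, d = 25))
  expect_equal(tx$richness, 4)
  expect_equal(tx$shannon, log(4))
  expect_equal(tx$evenness, 1)

  one <- taxonomic_indices(c(a = 50))
  expect_equal(one$shannon, 0)
  expect_true(is.na(one$evenness))

  # scale invariance of relative abundances
  expect_equal(taxonomic_indices(c(a = 10, b = 30))$shannon,
               taxonomic_indices(c(a = 1, b = 3))$shannon)

  set.seed(41)
  for (i in 1:10) {
    cv <- runif(sample(2:8, 1), 1, 60)
    names(cv) <- paste0("t", seq_along(cv))
    h <- taxonomic_indices(cv)$shannon
    expect_lte(h, log(length(cv)) + 1e-12)
  }
})

test_that("functional indices obey their gates and oracles", {
  proj <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1))
  # FRic equals the shoelace oracle for the right triangle
  fx <- functional_indices(c(a = 30, b = 30, c = 30), proj,
                           coverage_threshold = 0.8)
  expect_equal(fx$fric, 0.5)

  # three equidistant species, equal abundances: FEve = 1
  eq <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(3) / 2))
  fe <- functional_indices(c(a = 20, b = 20, c = 20), eq, 0.8)
  expect_equal(fe$feve, 1)
  expect_gte(fe$fdiv, 0); expect_lte(fe$fdiv, 1)

  # coverage gate: trait-covered species at 70% of total cover
  proj2 <- rbind(a = c(0, 0), b = c(1, 0))
  gated <- functional_indices(c(a = 30, b = 30, zz = 55), proj2, 0.8)
  expect_true(is.na(gated$fric) && is.na(gated$feve) && is.na(gated$fdiv))
  expect_equal(gated$reason, "trait_coverage_below_threshold")

  # S <= m: no hull
  small <- functional_indices(c(a = 30, b = 30), proj, 0.8)
  expect_true(is.na(small$fric))
  expect_equal(small$reason, "too_few_species_for_hull")
})

test_that("FEve and FDiv stay in [0,1]; FRic grows with an outside species", {
  set.seed(42)
  for (i in 1:10) {
    s <- sample(4:9, 1)
    proj <- matrix(rnorm(2 * s), s, 2,
                   dimnames = list(paste0("t", 1:s), NULL))
    cv <- runif(s, 5, 50); names(cv) <- rownames(proj)
    fx <- functional_indices(cv, proj, 0)
    if (!is.na(fx$feve)) { expect_gte(fx$feve, 0); expect_lte(fx$feve, 1) }
    if (!is.na(fx$fdiv)) { expect_gte(fx$fdiv, 0); expect_lte(fx$fdiv, 1) }
    proj2 <- rbind(proj, far = apply(proj, 2, max) + 2)
    cv2 <- c(cv, far = 10)
    fx2 <- functional_indices(cv2, proj2, 0)
    expect_gt(fx2$fric, fx$fric)
  }
})

test_that("phylogenetic indices match brute-force path-length oracles", {
  # two leaves 1.0 from the root
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  px <- phylogenetic_indices(c(A = 50, B = 50), t2)
  expect_equal(px$faith_pd, 2)
  expect_equal(px$mpd, 2)
  expect_equal(px$mntd, 2)

  set.seed(43)
  for (i in 1:5) {
    tree <- ape::rphylo(8, 1, 0)
    tree$tip.label <- paste0("t", 1:8)
    taxa <- sample(tree$tip.label, 4)
    cv <- setNames(runif(4, 5, 50), taxa)
    px <- phylogenetic_indices(cv, tree)
    pairs <- combn(taxa, 2)
    dists <- apply(pairs, 2, function(p) brute_path_length(tree, p[1], p[2]))
    expect_equal(px$mpd, mean(dists))
    nn <- vapply(taxa, function(a) {
      min(vapply(setdiff(taxa, a), function(b) brute_path_length(tree, a, b), 0))
    }, 0)
    expect_equal(px$mntd, mean(nn))
    expect_equal(px$faith_pd, brute_faith_pd(tree, taxa))
    expect_lte(px$mntd, px$mpd + 1e-12)
    # cross-check against the established implementation
    cm <- matrix(0, 1, 8, dimnames = list("s", tree$tip.label))
    cm[1, taxa] <- 1
    expect_equal(px$faith_pd,
                 picante::pd(cm, tree, include.root = TRUE)$PD)
    expect_equal(px$mpd,
                 picante::mpd(cm, ape::cophenetic.phylo(tree)))
    expect_equal(px$mntd,
                 picante::mntd(cm, ape::cophenetic.phylo(tree)))
  }
})

test_that("phylogenetic completeness gate and monotonicity hold", {
  tree <- toy_tree()
  gated <- phylogenetic_indices(c(Festuca_rubra = 30, Unknown_sp = 10), tree)
  expect_true(is.na(gated$faith_pd))
  expect_equal(gated$reason, "taxon_missing_from_tree")

  cv3 <- c(Festuca_rubra = 30, Poa_pratensis = 20, Picea_abies = 10)
  cv4 <- c(cv3, Betula_pendula = 5)
  expect_gte(phylogenetic_indices(cv4, tree)$faith_pd,
             phylogenetic_indices(cv3, tree)$faith_pd)

  bad <- tree; bad$edge.length[1] <- -1
  expect_error(phylogenetic_indices(cv3, bad), "negative branch lengths")
})

test_that("abundance weighting of mpd/mntd uses relative covers", {
  tree <- toy_tree()
  cv <- c(Festuca_rubra = 60, Poa_pratensis = 20, Picea_abies = 20)
  d <- ape::cophenetic.phylo(tree)[names(cv), names(cv)]
  p <- cv / sum(cv)
  w <- outer(p, p); diag(w) <- 0
  exp_mpd <- sum(w * d) / sum(w)
  nn <- apply(d + diag(Inf, 3), 1, min)
  exp_mntd <- sum(p * nn)
  px <- phylogenetic_indices(cv, tree, abundance_weighted = TRUE)
  expect_equal(px$mpd, exp_mpd)
  expect_equal(px$mntd, exp_mntd)
})

test_that("group indices use the overlap combination and handle absence", {
  cv <- c(a = 30, b = 30, c = 10)
  expect_equal(group_indices(cv, c("a", "b")),
               list(n = 2L, cover = 51))
  expect_equal(group_indices(cv, c("zz")), list(n = 0L, cover = 0))
  expect_lte(group_indices(cv, c("a", "b"))$cover,
             total_vegetation_cover(cv))
})

test_that("community-weighted niche width averages and gates correctly", {
  w <- c(a = 0.8, b = 0.7, c = 0.9, d = NA)
  expect_equal(cwm_niche_width(c(a = 40), w)$cwm, 0.8)
  expect_equal(cwm_niche_width(c(b = 25, c = 25), w)$cwm, 0.8)
  gated <- cwm_niche_width(c(b = 30, d = 60), w)
  expect_true(is.na(gated$cwm))
  expect_equal(gated$reason, "niche_coverage_below_threshold")
})

test_that("compute_diversity assembles all families with reasons", {
  ds <- toy_dataset()
  ds$traits <- prepare_traits(ds$traits)
  nw <- data.frame(taxon = rownames(ds$traits),
                   niche_width = c(0.8, 0.85, 0.7, 0.9, 0.75, 0.95),
                   niche_class = c("intermediate", "generalist", "specialist",
                                   "generalist", "specialist", "intermediate"),
                   stringsAsFactors = FALSE)
  div <- compute_diversity(ds, niche_table = nw, m_axes = 2)
  expect_equal(nrow(div), 4)
  expect_true(all(c("richness", "shannon", "fric", "faith_pd",
                    "n_threatened", "cwm_niche_width") %in% names(div)))
  expect_equal(div$richness[div$obs_id == "o1"], 3)
  # layer combination happens before indices: duplicate taxon across layers
  comm <- toy_community()
  extra <- comm[comm$obs_id == "o1" & comm$taxon == "Festuca_rubra", ]
  extra$layer <- "shrub"; extra$cover <- 40
  ds2 <- toy_dataset(); ds2$community <- rbind(comm, extra)
  div2 <- compute_diversity(ds2, indices = "taxonomic")
  expect_equal(div2$richness[div2$obs_id == "o1"], 3)
  # overlap-combined Festuca cover: 100*(1-0.6^2) = 64
  expect_equal(div2$total_cover[div2$obs_id == "o1"],
               combine_layer_cover(c(combine_layer_cover(c(40, 40)), 30, 10)))
})
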