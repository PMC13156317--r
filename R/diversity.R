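#' Taxonomic diversity of one community
#'
#' @param covers named numeric vector of layer-combined percent covers
#'   (names are taxa), all > 0.
#' @return list with `richness`, `shannon` (natural log), `evenness`
#'   (Pielou J, `NA` for a single species), and `total_cover`
#'   (overlap-combined).
#' @export
taxonomic_indices <- function(covers) {
  s <- length(covers)
  if (s == 0L) {
    return(list(richness = 0L, shannon = NA_real_, evenness = NA_real_,
                total_cover = 0))
  }
  p <- covers / sum(covers)
  h <- -sum(p * log(p))
  list(
    richness = s,
    shannon = h,
    evenness = if (s > 1L) h / log(s) else NA_real_,
    total_cover = total_vegetation_cover(covers)
  )
}

#' Global trait-space projection shared by all observations
#'
#' Principal-component scores of the standardized trait matrix, computed
#' once over the whole species pool so that hull volumes are comparable
#' across observations. Species with any missing trait are excluded.
#'
#' @param traits standardized trait matrix (see [prepare_traits()]).
#' @param m_axes number of retained axes (default 4).
#' @return score matrix (species x m_axes) with taxa rownames.
#' @export
trait_projection <- function(traits, m_axes = 4L) {
  ok <- complete.cases(traits)
  x <- traits[ok, , drop = FALSE]
  m_axes <- min(m_axes, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(m_axes), drop = FALSE]
  rownames(scores) <- rownames(x)
  scores
}

#' Functional richness, evenness, and divergence of one community
#'
#' Computed in a shared m-axis trait space (see [trait_projection()]),
#' gated on trait completeness: when the combined cover of species with
#' trait data falls below `coverage_threshold` of the total vegetation
#' cover, all three indices are missing. FRic is the convex-hull volume of
#' the present species (missing when S <= m or the points are degenerate);
#' FEve measures the regularity of abundance along the minimum spanning
#' tree (missing when S < 3); FDiv is the abundance-weighted spread of
#' species around the centre of gravity of the hull vertices.
#'
#' @param covers named numeric vector of layer-combined covers.
#' @param projection trait-space score matrix from [trait_projection()].
#' @param coverage_threshold minimum trait-data cover fraction (default 0.8).
#' @return list with `fric`, `feve`, `fdiv`, and `reason` (NA when computed).
#' @export
functional_indices <- function(covers, projection, coverage_threshold = 0.80) {
  out <- list(fric = NA_real_, feve = NA_real_, fdiv = NA_real_,
              reason = NA_character_)
  taxa <- names(covers)
  with_traits <- intersect(taxa, rownames(projection))
  total <- total_vegetation_cover(covers)
  if (total == 0) { out$reason <- "empty_community"; return(out) }
  covered <- total_vegetation_cover(covers[with_traits])
  if (covered < coverage_threshold * total) {
    out$reason <- "trait_coverage_below_threshold"
    return(out)
  }
  pts <- projection[with_traits, , drop = FALSE]
  w <- covers[with_traits] / sum(covers[with_traits])
  s <- length(with_traits)
  m <- ncol(pts)

  hull <- if (s > m) convhull_volume(pts) else
    list(volume = NA_real_, vertices = integer(0), degenerate = TRUE)
  if (!hull$degenerate) {
    out$fric <- hull$volume
  } else {
    out$reason <- if (s <= m) "too_few_species_for_hull" else "degenerate_hull"
  }

  if (s >= 3L) {
    d <- as.matrix(dist(pts))
    mst <- vegan::spantree(as.dist(d))
    from <- seq_len(s)[-1L]
    to <- mst$kid
    ew <- d[cbind(from, to)] / (w[from] + w[to])
    pew <- ew / sum(ew)
    thr <- 1 / (s - 1)
    out$feve <- (sum(pmin(pew, thr)) - thr) / (1 - thr)
  }

  if (!hull$degenerate && length(hull$vertices)) {
    g <- colMeans(pts[hull$vertices, , drop = FALSE])
    di <- sqrt(rowSums(sweep(pts, 2L, g)^2))
    dg <- mean(di)
    delta_d <- sum(w * (di - dg))
    delta_ad <- sum(w * abs(di - dg))
    out$fdiv <- (delta_d + dg) / (delta_ad + dg)
  }
  out
}

#' Phylogenetic diversity of one community
#'
#' Faith's phylogenetic diversity (sum of branch lengths of the minimal
#' subtree spanning the taxa, root path included by default), mean pairwise
#' phylogenetic distance, and mean nearest taxon distance. Missing when any
#' community taxon is absent from the tree (completeness gate) and for
#' single-species communities (mpd/mntd).
#'
#' @param covers named numeric vector of layer-combined covers.
#' @param tree an [ape::phylo] tree with non-negative branch lengths.
#' @param abundance_weighted if `TRUE`, mpd weights pairs by
#'   \eqn{p_i p_j} and mntd weights nearest-neighbour distances by
#'   \eqn{p_i}.
#' @param include_root include the path from the community's most recent
#'   common ancestor up to the tree root in Faith PD (default `TRUE`).
#' @return list with `faith_pd`, `mpd`, `mntd`, `reason`.
#' @export
phylogenetic_indices <- function(covers, tree, abundance_weighted = FALSE,
                                 include_root = TRUE) {
  out <- list(faith_pd = NA_real_, mpd = NA_real_, mntd = NA_real_,
              reason = NA_character_)
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  taxa <- names(covers)
  if (length(taxa) == 0L) { out$reason <- "empty_community"; return(out) }
  if (!all(taxa %in% tree$tip.label)) {
    out$reason <- "taxon_missing_from_tree"
    return(out)
  }
  depths <- ape::node.depth.edgelength(tree)
  if (length(taxa) == 1L) {
    out$faith_pd <- if (include_root) {
      depths[match(taxa, tree$tip.label)]
    } else 0
    out$reason <- "single_species_no_pairwise"
    return(out)
  }
  sub <- ape::keep.tip(tree, taxa)
  pd <- sum(sub$edge.length)
  if (include_root) {
    mrca <- if (length(taxa) > 1L) ape::getMRCA(tree, taxa) else NULL
    if (!is.null(mrca)) pd <- pd + depths[mrca]
  }
  out$faith_pd <- pd

  d <- ape::cophenetic.phylo(sub)[taxa, taxa]
  p <- covers / sum(covers)
  if (abundance_weighted) {
    wmat <- outer(p, p)
    diag(wmat) <- 0
    out$mpd <- sum(wmat * d) / sum(wmat)
    nn <- apply(d + diag(Inf, nrow(d)), 1L, min)
    out$mntd <- sum(p * nn) / sum(p)
  } else {
    out$mpd <- mean(d[upper.tri(d)])
    nn <- apply(d + diag(Inf, nrow(d)), 1L, min)
    out$mntd <- mean(nn)
  }
  out
}

#' Richness and combined cover of a species group
#'
#' Same arithmetic as for the whole community, restricted to a member set
#' (threatened, non-native, specialist, or generalist taxa): richness is
#' the count of member taxa present, cover the overlap combination of their
#' covers. An absent group yields (0, 0).
#'
#' @param covers named numeric vector of layer-combined covers.
#' @param members character vector of group member taxa.
#' @return list with `n` and `cover`.
#' @export
group_indices <- function(covers, members) {
  present <- intersect(names(covers), members)
  list(n = length(present),
       cover = if (length(present)) total_vegetation_cover(covers[present]) else 0)
}

#' Community-weighted mean niche width
#'
#' Relative-cover weighted mean of species niche widths, gated on coverage:
#' missing when the species with width estimates jointly cover less than
#' `coverage_threshold` of the total vegetation cover.
#'
#' @param covers named numeric vector of layer-combined covers.
#' @param widths named numeric vector of niche widths (may carry NAs).
#' @param coverage_threshold minimum covered fraction (default 0.8).
#' @return list with `cwm` and `reason`.
#' @export
cwm_niche_width <- function(covers, widths, coverage_threshold = 0.80) {
  scored <- names(widths)[!is.na(widths)]
  present <- intersect(names(covers), scored)
  total <- total_vegetation_cover(covers)
  if (total == 0) return(list(cwm = NA_real_, reason = "empty_community"))
  covered <- if (length(present)) total_vegetation_cover(covers[present]) else 0
  if (covered < coverage_threshold * total) {
    return(list(cwm = NA_real_, reason = "niche_coverage_below_threshold"))
  }
  cw <- covers[present]
  list(cwm = sum(cw * widths[present]) / sum(cw), reason = NA_character_)
}

#' Per-observation diversity table for a whole dataset
#'
#' Layer-combines covers per taxon within every observation and computes
#' the requested index families, recording the reason whenever a gated
#' index is missing.
#'
#' @param dataset an `rsv_dataset`.
#' @param niche_table optional [estimate_niche_widths()] output with a
#'   `niche_class` column (see [classify_niche_categories()]).
#' @param indices character vector among `"taxonomic"`, `"functional"`,
#'   `"phylogenetic"`, `"groups"`, `"cwm"`, or `"all"`.
#' @param m_axes trait-space dimensionality (default 4).
#' @param coverage_threshold trait/niche cover gate (default 0.8).
#' @param abundance_weighted,include_root see [phylogenetic_indices()].
#' @return data frame, one row per observation, with an attached `reasons`
#'   attribute (data frame `obs_id`, `index`, `reason`).
#' @export
compute_diversity <- function(dataset, niche_table = NULL, indices = "all",
                              m_axes = 4L, coverage_threshold = 0.80,
                              abundance_weighted = FALSE, include_root = TRUE) {
  all_fams <- c("taxonomic", "functional", "phylogenetic", "groups", "cwm")
  fams <- if (identical(indices, "all")) all_fams else match.arg(indices,
    all_fams, several.ok = TRUE)
  comm <- dataset$community
  comm <- comm[!is.na(comm$cover) & comm$cover > 0, , drop = FALSE]

  projection <- NULL
  if ("functional" %in% fams) {
    if (is.null(dataset$traits)) stop("functional indices need traits")
    tr <- dataset$traits
    if (!isTRUE(attr(tr, "standardized"))) tr <- prepare_traits(tr)
    projection <- trait_projection(tr, m_axes)
  }
  if ("phylogenetic" %in% fams && is.null(dataset$phylogeny)) {
    stop("phylogenetic indices need a tree")
  }
  widths <- classes <- NULL
  if (!is.null(niche_table)) {
    widths <- setNames(niche_table$niche_width, niche_table$taxon)
    if ("niche_class" %in% names(niche_table)) {
      classes <- setNames(niche_table$niche_class, niche_table$taxon)
    }
  }
  attrs <- dataset$attributes
  threatened_taxa <- if (!is.null(attrs)) attrs$taxon[attrs$threatened %in% TRUE] else character(0)
  nonnative_taxa <- if (!is.null(attrs)) attrs$taxon[attrs$non_native %in% TRUE] else character(0)
  specialist_taxa <- if (!is.null(classes)) names(classes)[classes == "specialist"] else character(0)
  generalist_taxa <- if (!is.null(classes)) names(classes)[classes == "generalist"] else character(0)

  meta <- unique(comm[, c("obs_id", "series_id", "year")])
  meta <- meta[order(meta$series_id, meta$year, meta$obs_id), , drop = FALSE]
  rows <- vector("list", nrow(meta))
  reasons <- list()
  note <- function(obs, index, reason) {
    reasons[[length(reasons) + 1L]] <<- data.frame(
      obs_id = obs, index = index, reason = reason, stringsAsFactors = FALSE)
  }
  comm_by_obs <- split(comm[, c("taxon", "cover")], comm$obs_id)

  for (i in seq_len(nrow(meta))) {
    obs <- meta$obs_id[i]
    rec <- comm_by_obs[[obs]]
    covers <- if (is.null(rec)) numeric(0) else
      tapply(rec$cover, rec$taxon, combine_layer_cover)
    covers <- covers[covers > 0]
    row <- list(obs_id = obs, series_id = meta$series_id[i],
                year = meta$year[i])
    if ("taxonomic" %in% fams) {
      tx <- taxonomic_indices(covers)
      row <- c(row, tx)
      if (tx$richness == 1L) note(obs, "evenness", "single_species")
    }
    if ("functional" %in% fams) {
      fx <- functional_indices(covers, projection, coverage_threshold)
      row <- c(row, fx[c("fric", "feve", "fdiv")])
      if (!is.na(fx$reason)) note(obs, "functional", fx$reason)
    }
    if ("phylogenetic" %in% fams) {
      px <- phylogenetic_indices(covers, dataset$phylogeny,
                                 abundance_weighted, include_root)
      row <- c(row, px[c("faith_pd", "mpd", "mntd")])
      if (!is.na(px$reason)) note(obs, "phylogenetic", px$reason)
    }
    if ("groups" %in% fams) {
      gth <- group_indices(covers, threatened_taxa)
      gnn <- group_indices(covers, nonnative_taxa)
      gsp <- group_indices(covers, specialist_taxa)
      gge <- group_indices(covers, generalist_taxa)
      row <- c(row, list(
        n_threatened = gth$n, cover_threatened = gth$cover,
        n_nonnative = gnn$n, cover_nonnative = gnn$cover,
        n_specialist = gsp$n, cover_specialist = gsp$cover,
        n_generalist = gge$n, cover_generalist = gge$cover))
    }
    if ("cwm" %in% fams) {
      if (is.null(widths)) stop("cwm needs a niche_table")
      cw <- cwm_niche_width(covers, widths, coverage_threshold)
      row <- c(row, list(cwm_niche_width = cw$cwm))
      if (!is.na(cw$reason)) note(obs, "cwm_niche_width", cw$reason)
    }
    rows[[i]] <- row
  }
  fields <- names(rows[[1L]])
  res <- as.data.frame(
    setNames(lapply(fields, function(nm) {
      unlist(lapply(rows, function(r) {
        v <- r[[nm]]
        if (is.null(v)) NA else unname(v)
      }), use.names = FALSE)
    }), fields),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "reasons") <- if (length(reasons)) do.call(rbind, reasons) else
    data.frame(obs_id = character(0), index = character(0),
               reason = character(0))
  res
}
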