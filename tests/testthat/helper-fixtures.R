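# Shared in-code fixtures: a tiny two-series community and helpers used
# across the unit tests.

toy_community <- function() {
  data.frame(
    obs_id = c("o1", "o1", "o1", "o2", "o2", "o3", "o3", "o4", "o4"),
    series_id = c("s1", "s1", "s1", "s1", "s1", "s2", "s2", "s2", "s2"),
    year = c(1990L, 1990L, 1990L, 2000L, 2000L, 1995L, 1995L, 2005L, 2005L),
    plot_size = 25,
    taxon = c("Festuca_rubra", "Poa_pratensis", "Trifolium_repens",
              "Festuca_rubra", "Poa_pratensis",
              "Betula_pendula", "Vaccinium_myrtillus",
              "Betula_pendula", "Picea_abies"),
    layer = "herb",
    cover = c(40, 30, 10, 45, 25, 60, 20, 55, 15),
    eunis_l1 = c(rep("R", 5), rep("T", 4)),
    eunis_l3 = c(rep("R22", 5), rep("T18", 4)),
    design = "permanent",
    manipulated = FALSE,
    stringsAsFactors = FALSE
  )
}

toy_tree <- function() {
  ape::read.tree(text = paste0(
    "((Festuca_rubra:1,Poa_pratensis:1):2,((Trifolium_repens:2,",
    "Vaccinium_myrtillus:2):0.5,(Betula_pendula:1.5,Picea_abies:1.5):1):0.5);"
  ))
}

toy_traits <- function() {
  set.seed(99)
  taxa <- c("Festuca_rubra", "Poa_pratensis", "Trifolium_repens",
            "Betula_pendula", "Vaccinium_myrtillus", "Picea_abies")
  m <- matrix(exp(rnorm(18)), 6, 3,
              dimnames = list(taxa, c("height", "sla", "seed_mass")))
  m
}

toy_attributes <- function() {
  data.frame(
    taxon = c("Festuca_rubra", "Poa_pratensis", "Trifolium_repens",
              "Betula_pendula", "Vaccinium_myrtillus", "Picea_abies"),
    threatened = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    non_native = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

toy_dataset <- function() {
  rsv_dataset(toy_community(), traits = toy_traits(),
              phylogeny = toy_tree(), attributes = toy_attributes())
}

# shoelace polygon area of the 2D convex hull (independent oracle)
shoelace_hull_area <- function(pts) {
  ch <- grDevices::chull(pts)
  xs <- pts[ch, 1L]; ys <- pts[ch, 2L]
  abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)) / 2
}

# brute-force patristic distance: sum of edge lengths along the node path
brute_path_length <- function(tree, t1, t2) {
  i1 <- match(t1, tree$tip.label); i2 <- match(t2, tree$tip.label)
  path <- ape::nodepath(tree, i1, i2)
  len <- 0
  for (k in seq_len(length(path) - 1L)) {
    e <- which(tree$edge[, 1L] == path[k] & tree$edge[, 2L] == path[k + 1L] |
                 tree$edge[, 2L] == path[k] & tree$edge[, 1L] == path[k + 1L])
    len <- len + tree$edge.length[e]
  }
  len
}

# brute-force Faith PD: union of edges on root-to-tip paths
brute_faith_pd <- function(tree, taxa) {
  root <- ape::Ntip(tree) + 1L
  edges <- integer(0)
  for (t in taxa) {
    path <- ape::nodepath(tree, root, match(t, tree$tip.label))
    for (k in seq_len(length(path) - 1L)) {
      e <- which(tree$edge[, 1L] == path[k] & tree$edge[, 2L] == path[k + 1L])
      edges <- union(edges, e)
    }
  }
  sum(tree$edge.length[edges])
}
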