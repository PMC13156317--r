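#' Construct a resurvey dataset object
#'
#' The central container of the package: a long community table (one row per
#' observation x taxon x layer), a trait matrix, a phylogeny, and a
#' species-attribute table. Taxon names are treated as already-harmonized
#' keys; taxa missing from traits, tree, or attributes are retained with
#' missing annotations.
#'
#' @param community data frame with columns `obs_id`, `series_id`, `year`,
#'   `plot_size`, `taxon`, `layer`, `cover`, `eunis_l1`, `eunis_l3`,
#'   `design`, `manipulated`, and optionally `plot_id` (defaults to
#'   `series_id` when absent).
#' @param traits numeric matrix with taxa rownames, or `NULL`.
#' @param phylogeny an [ape::phylo] tree, or `NULL`.
#' @param attributes data frame with columns `taxon`, `threatened`,
#'   `non_native`, or `NULL`.
#' @return an object of class `rsv_dataset`.
#' @export
rsv_dataset <- function(community, traits = NULL, phylogeny = NULL,
                        attributes = NULL) {
  required <- c("obs_id", "series_id", "year", "plot_size", "taxon", "layer",
                "cover", "eunis_l1", "eunis_l3", "design", "manipulated")
  miss <- setdiff(required, names(community))
  if (length(miss)) stop("community table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"plot_id" %in% names(community)) community$plot_id <- community$series_id
  bad <- which(!is.na(community$cover) &
                 (community$cover < 0 | community$cover > 100))
  if (length(bad)) {
    stop("cover outside [0, 100] in community rows: ",
         paste(head(bad, 10L), collapse = ", "))
  }
  key <- paste(community$obs_id, community$taxon, community$layer, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (obs_id, taxon, layer) in community rows: ",
         paste(head(which(duplicated(key)), 10L), collapse = ", "))
  }
  bad_year <- which(!is.na(community$year) &
                      (community$year < 1900 | community$year > 2100))
  if (length(bad_year)) {
    stop("year outside [1900, 2100] in rows: ",
         paste(head(bad_year, 10L), collapse = ", "))
  }
  if (!is.null(phylogeny)) {
    stopifnot(inherits(phylogeny, "phylo"))
    if (any(phylogeny$edge.length < 0)) stop("negative branch lengths")
    if (anyDuplicated(phylogeny$tip.label)) stop("duplicate tip labels")
  }
  structure(
    list(community = community, traits = traits, phylogeny = phylogeny,
         attributes = attributes),
    class = "rsv_dataset"
  )
}

#' @export
print.rsv_dataset <- function(x, ...) {
  comm <- x$community
  cat("<rsv_dataset>\n")
  cat(sprintf("  %d series, %d observations, %d taxa, %d records\n",
              length(unique(comm$series_id)), length(unique(comm$obs_id)),
              length(unique(comm$taxon)), nrow(comm)))
  cat(sprintf("  traits: %s; phylogeny: %s; attributes: %s\n",
              if (is.null(x$traits)) "none" else paste(dim(x$traits), collapse = " x "),
              if (is.null(x$phylogeny)) "none" else paste(length(x$phylogeny$tip.label), "tips"),
              if (is.null(x$attributes)) "none" else paste(nrow(x$attributes), "taxa")))
  invisible(x)
}

#' Load a resurvey dataset from delimited files
#'
#' @param community_path CSV long community table (see [rsv_dataset()]).
#' @param traits_path optional CSV, taxa in the first column.
#' @param tree_path optional newick file.
#' @param attributes_path optional CSV with columns `taxon`, `threatened`,
#'   `non_native` and optionally `niche_width`, `niche_class`.
#' @return validated `rsv_dataset` with a `load_report` attribute counting
#'   series, observations, and taxa.
#' @export
load_dataset <- function(community_path, traits_path = NULL,
                         tree_path = NULL, attributes_path = NULL) {
  comm <- read.csv(community_path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  comm$manipulated <- as.logical(comm$manipulated)
  traits <- NULL
  if (!is.null(traits_path)) {
    tr <- read.csv(traits_path, stringsAsFactors = FALSE, check.names = FALSE)
    traits <- as.matrix(tr[, -1, drop = FALSE])
    rownames(traits) <- tr[[1]]
    storage.mode(traits) <- "double"
  }
  tree <- if (!is.null(tree_path)) ape::read.tree(tree_path) else NULL
  attrs <- NULL
  if (!is.null(attributes_path)) {
    attrs <- read.csv(attributes_path, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
    attrs$threatened <- as.logical(attrs$threatened)
    attrs$non_native <- as.logical(attrs$non_native)
  }
  ds <- rsv_dataset(comm, traits, tree, attrs)
  attr(ds, "load_report") <- c(
    series = length(unique(comm$series_id)),
    observations = length(unique(comm$obs_id)),
    taxa = length(unique(comm$taxon)),
    records = nrow(comm)
  )
  ds
}

#' Write result tables and a run manifest
#'
#' Each table is written as a CSV with header, missing values as empty
#' fields. A machine-readable `manifest.json` (config echo, seed, package
#' and R versions) is always written; it carries no wall-clock fields, so
#' identical inputs yield byte-identical outputs.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @param config optional list echoed into the manifest.
#' @param seed optional integer echoed into the manifest.
#' @return invisible character vector of written file paths.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory not writable: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "resurveytrends",
    version = as.character(packageVersion("resurveytrends")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    tables = names(tables)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(paths, mp))
}

#' Validate a loaded dataset without modifying it
#'
#' Report-only checks: year range and per-series ordering feasibility, cover
#' range, orphan taxa (present in records but absent from traits, tree, and
#' attributes alike), and EUNIS level-3 / level-1 prefix consistency.
#'
#' @param dataset an `rsv_dataset`.
#' @return data frame with columns `check`, `pass`, `n_fail`.
#' @export
validate_dataset <- function(dataset) {
  comm <- dataset$community
  n_bad_year <- sum(!is.na(comm$year) & (comm$year < 1900 | comm$year > 2100))
  n_bad_cover <- sum(!is.na(comm$cover) & (comm$cover < 0 | comm$cover > 100))

  known <- character(0)
  if (!is.null(dataset$traits)) known <- union(known, rownames(dataset$traits))
  if (!is.null(dataset$phylogeny)) known <- union(known, dataset$phylogeny$tip.label)
  if (!is.null(dataset$attributes)) known <- union(known, dataset$attributes$taxon)
  orphans <- setdiff(unique(comm$taxon), known)

  obs <- unique(comm[, c("obs_id", "eunis_l1", "eunis_l3")])
  incons <- !is.na(obs$eunis_l3) &
    (is.na(obs$eunis_l1) | substr(obs$eunis_l3, 1L, 1L) != obs$eunis_l1)

  data.frame(
    check = c("year_range", "cover_range", "orphan_taxa", "eunis_prefix"),
    pass = c(n_bad_year == 0L, n_bad_cover == 0L, length(orphans) == 0L,
             sum(incons) == 0L),
    n_fail = c(n_bad_year, n_bad_cover, length(orphans), sum(incons)),
    stringsAsFactors = FALSE
  )
}
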