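#' Default habitat-change trajectory map and complexity ranks
#'
#' The mapping table resolves pairs of (initial, final) EUNIS level-3 code
#' prefixes to a trajectory category; longest combined prefix wins. Pairs not
#' covered by a rule fall back to level-1 vegetation-complexity ranks:
#' sparsely vegetated and man-made habitats < grasslands < shrublands and
#' heathlands < forests, with inland waters and mires each ranked on their
#' own scale (cross-scale shifts are undirected). A rank increase is
#' succession, a decrease disturbance, and equal or incomparable ranks with
#' different codes are "other". The shipped default encodes a small set of
#' undirected within-class shifts (e.g. wet to dry heath) as "other"; the
#' full expert mapping can be supplied as a CSV with columns
#' `initial_prefix`, `final_prefix`, `category` via [read_trajectory_map()].
#'
#' @return list with elements `rules` (data frame) and `ranks` (data frame
#'   with columns `l1`, `group`, `rank`).
#' @export
default_trajectory_map <- function() {
  rules <- data.frame(
    initial_prefix = c("S41", "S42"),
    final_prefix   = c("S42", "S41"),
    category       = c("other", "other"),
    stringsAsFactors = FALSE
  )
  ranks <- data.frame(
    l1 = c("U", "V", "R", "S", "T", "P", "Q", "N"),
    group = c("terrestrial", "terrestrial", "terrestrial", "terrestrial",
              "terrestrial", "waters", "mires", "coastal"),
    rank = c(1, 1, 2, 3, 4, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  list(rules = rules, ranks = ranks)
}

#' Read a trajectory mapping table from CSV
#'
#' @param path CSV with columns `initial_prefix`, `final_prefix`, `category`.
#' @param ranks optional replacement for the default level-1 rank table.
#' @return a trajectory map list as in [default_trajectory_map()].
#' @export
read_trajectory_map <- function(path, ranks = default_trajectory_map()$ranks) {
  rules <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("initial_prefix", "final_prefix", "category") %in% names(rules)))
  list(rules = rules, ranks = ranks)
}

trajectory_categories <- c("stable", "succession", "disturbance", "other",
                           "unclassifiable")

#' Classify the habitat-change trajectory of one time series
#'
#' @param initial_l3,final_l3 EUNIS level-3 codes at the first and last
#'   observation, or `NA`.
#' @param map trajectory map (default [default_trajectory_map()]).
#' @return one of `"stable"`, `"succession"`, `"disturbance"`, `"other"`,
#'   `"unclassifiable"`.
#' @examples
#' classify_trajectory("R22", "T18") # grassland to forest: succession
#' @export
classify_trajectory <- function(initial_l3, final_l3,
                                map = default_trajectory_map()) {
  if (is.na(initial_l3) || is.na(final_l3)) return("unclassifiable")
  ok_code <- function(x) grepl("^[A-Za-z][A-Za-z0-9]*$", x)
  if (!ok_code(initial_l3) || !ok_code(final_l3)) {
    stop("malformed EUNIS code: ", initial_l3, " / ", final_l3)
  }
  if (initial_l3 == final_l3) return("stable")

  rules <- map$rules
  if (nrow(rules)) {
    hit <- startsWith(initial_l3, rules$initial_prefix) &
      startsWith(final_l3, rules$final_prefix)
    if (any(hit)) {
      cand <- rules[hit, , drop = FALSE]
      score <- nchar(cand$initial_prefix) + nchar(cand$final_prefix)
      return(cand$category[which.max(score)])
    }
  }

  ranks <- map$ranks
  r1 <- ranks[match(substr(initial_l3, 1L, 1L), ranks$l1), ]
  r2 <- ranks[match(substr(final_l3, 1L, 1L), ranks$l1), ]
  if (anyNA(r1$rank) || anyNA(r2$rank) || r1$group != r2$group) return("other")
  if (r2$rank > r1$rank) return("succession")
  if (r2$rank < r1$rank) return("disturbance")
  "other"
}

#' Assign trajectories to every series of a dataset
#'
#' Uses the EUNIS level-3 codes of the first and last observation of each
#' series (classification depends on the endpoints only).
#'
#' @param dataset an `rsv_dataset`.
#' @param map trajectory map.
#' @return data frame with columns `series_id`, `initial_l3`, `final_l3`,
#'   `trajectory`.
#' @export
assign_trajectories <- function(dataset, map = default_trajectory_map()) {
  comm <- dataset$community
  obs <- unique(comm[, c("series_id", "obs_id", "year", "eunis_l3")])
  out <- lapply(split(obs, obs$series_id), function(so) {
    so <- so[order(so$year, so$obs_id), , drop = FALSE]
    ini <- so$eunis_l3[1L]; fin <- so$eunis_l3[nrow(so)]
    data.frame(series_id = so$series_id[1L], initial_l3 = ini,
               final_l3 = fin,
               trajectory = classify_trajectory(ini, fin, map),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percentage shares of trajectory categories (reporting arithmetic)
#'
#' Turns per-category counts into the percentage shares used in reporting,
#' rounded to one decimal place.
#'
#' @param counts named integer vector (names are categories) or a character
#'   vector of per-series categories to be tabulated.
#' @param total denominator; defaults to `sum(counts)`.
#' @return data frame with columns `category`, `n`, `share_pct`.
#' @export
trajectory_shares <- function(counts, total = NULL) {
  if (is.character(counts) || is.factor(counts)) {
    counts <- table(factor(counts, levels = trajectory_categories))
  }
  n <- as.numeric(counts)
  if (is.null(total)) total <- sum(n)
  data.frame(
    category = names(counts),
    n = n,
    share_pct = percent_share(n, total),
    stringsAsFactors = FALSE
  )
}

#' Percentage share rounded to reporting precision
#'
#' @param n count(s).
#' @param total denominator.
#' @param digits decimal places (default 1, the reporting convention).
#' @return numeric percentage(s).
#' @export
percent_share <- function(n, total, digits = 1L) {
  round(100 * n / total, digits)
}
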