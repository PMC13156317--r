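#' Configuration for the synthetic resurvey-data generator
#'
#' Defaults mirror the structure of large European resurvey compilations:
#' most series hold two (55%), three (17.7%), or four (8.6%) observations;
#' series spans fall in 1-4 (10.3%), 5-10 (43.1%), 11-20 (18.1%), or
#' 21-103 (28.5%) years; trajectory categories mix as 23.6% stable, 5.7%
#' successional, 3.4% disturbance, 18.9% other, 48.5% unclassifiable; and
#' the default true trends are +0.2%/yr richness and +0.7%/yr species
#' cover. Traits emulate a 14-dimensional log-normal trait battery.
#'
#' @param n_species pool size (default 120).
#' @param n_habitats number of habitat pools (default 5; the first four
#'   form the complexity chain man-made < grassland < shrubland < forest,
#'   the fifth is a mire ranked on its own scale).
#' @param trait_dim number of traits (default 14).
#' @param trait_rho AR(1) correlation between neighbouring traits on the
#'   log scale (default 0.4).
#' @param birth_rate pure-birth rate of the simulated phylogeny.
#' @param p_threatened,p_nonnative Bernoulli flag probabilities.
#' @param affinity_concentration symmetric Dirichlet concentration of the
#'   species x habitat affinity rows: low values make specialists, high
#'   values generalists (default 1).
#' @param n_series number of time series (default 100).
#' @param obs_per_series_probs named probabilities of observation counts.
#' @param span_classes data frame (`lo`, `hi`, `p`) of span classes, years.
#' @param year_min,year_max calendar window for series start/end.
#' @param richness_log_trend true annual log-linear richness trend
#'   (default log(1.002)).
#' @param cover_log_trend true annual log-linear per-species cover trend
#'   (default log(1.007)).
#' @param cover_noise_sd lognormal multiplicative noise sd on covers.
#' @param turnover_rate expected composition swaps per year (default 0.1).
#' @param trajectory_mix named category proportions.
#' @param mean_initial_richness expected starting richness (default 14).
#' @param cover_meanlog,cover_sdlog lognormal baseline cover parameters.
#' @param two_layer_fraction fraction of species recorded in two layers.
#' @param p_semi_permanent probability a series is semi-permanent.
#' @param p_manipulated per-observation probability of the manipulation
#'   flag (default 0: a clean analysis set).
#' @param p_size_change probability a series triples its plot area on the
#'   last observation (default 0; used to exercise the area filter).
#' @param seed integer seed; the pool consumes `seed`, the series
#'   simulation `seed + 1`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 120L, n_habitats = 5L, trait_dim = 14L,
                       trait_rho = 0.4, birth_rate = 1,
                       p_threatened = 0.12, p_nonnative = 0.08,
                       affinity_concentration = 1,
                       n_series = 100L,
                       obs_per_series_probs = c(
                         "2" = 0.55, "3" = 0.177, "4" = 0.086,
                         "5" = 0.187 / 6, "6" = 0.187 / 6, "7" = 0.187 / 6,
                         "8" = 0.187 / 6, "9" = 0.187 / 6, "10" = 0.187 / 6),
                       span_classes = data.frame(
                         lo = c(1, 5, 11, 21), hi = c(4, 10, 20, 103),
                         p = c(0.103, 0.431, 0.181, 0.285)),
                       year_min = 1920L, year_max = 2023L,
                       richness_log_trend = log(1.002),
                       cover_log_trend = log(1.007),
                       cover_noise_sd = 0.2, turnover_rate = 0.1,
                       trajectory_mix = c(stable = 0.236,
                                          succession = 0.057,
                                          disturbance = 0.034,
                                          other = 0.189,
                                          unclassifiable = 0.485),
                       mean_initial_richness = 14,
                       cover_meanlog = log(10), cover_sdlog = 1,
                       two_layer_fraction = 0.15,
                       p_semi_permanent = 0.3,
                       p_manipulated = 0, p_size_change = 0,
                       seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_series >= 1L, cfg$n_species >= 2L,
            all(cfg$trajectory_mix >= 0),
            all(unlist(cfg[c("p_threatened", "p_nonnative",
                             "p_semi_permanent", "p_manipulated",
                             "p_size_change")]) >= 0),
            all(unlist(cfg[c("p_threatened", "p_nonnative",
                             "p_semi_permanent", "p_manipulated",
                             "p_size_change")]) <= 1),
            is.finite(cfg$richness_log_trend), is.finite(cfg$cover_log_trend),
            cfg$turnover_rate >= 0, cfg$affinity_concentration > 0)
  cfg$trajectory_mix <- cfg$trajectory_mix / sum(cfg$trajectory_mix)
  class(cfg) <- "sim_config"
  cfg
}

# habitat templates: EUNIS-style level 1 / level 3 codes with complexity
# ranks; the first four form the terrestrial succession chain.
sim_habitat_table <- function(n_habitats) {
  templates <- data.frame(
    l1 = c("V", "R", "S", "T", "Q", "P", "U", "N"),
    l3 = c("V15", "R22", "S42", "T18", "Q22", "P16", "U32", "N12"),
    group = c("terrestrial", "terrestrial", "terrestrial", "terrestrial",
              "mires", "waters", "terrestrial", "coastal"),
    rank = c(1, 2, 3, 4, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  if (n_habitats > nrow(templates)) stop("at most 8 habitats supported")
  templates[seq_len(n_habitats), , drop = FALSE]
}

#' Generate a synthetic species pool
#'
#' Traits are multivariate log-normal with AR(1) correlation on the log
#' scale; the phylogeny is a pure-birth tree over the pool; threatened and
#' non-native flags are Bernoulli; habitat affinities are symmetric
#' Dirichlet rows (rows sum to 1).
#'
#' @param config a [sim_config()].
#' @return list of class `rsv_species_pool`: `taxa`, `traits` (raw),
#'   `phylogeny`, `attributes`, `affinity`, `home_layer`, `two_layer`,
#'   `habitats`.
#' @export
generate_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_species
  k <- config$trait_dim
  h <- config$n_habitats

  n_genera <- max(2L, ceiling(n / 3))
  genera <- sprintf("Genus%03d", seq_len(n_genera))
  taxa <- paste(sample(genera, n, replace = TRUE),
                sprintf("species%03d", seq_len(n)))

  sigma <- config$trait_rho^abs(outer(seq_len(k), seq_len(k), "-"))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("trait correlation matrix is not positive definite")
  mu <- rnorm(k, 0, 1)
  traits <- exp(MASS::mvrnorm(n, mu = mu, Sigma = sigma))
  rownames(traits) <- taxa
  colnames(traits) <- sprintf("trait%02d", seq_len(k))

  tree <- ape::rphylo(n, birth = config$birth_rate, death = 0)
  tree$tip.label <- taxa

  attributes <- data.frame(
    taxon = taxa,
    threatened = rbinom(n, 1L, config$p_threatened) == 1L,
    non_native = rbinom(n, 1L, config$p_nonnative) == 1L,
    stringsAsFactors = FALSE
  )

  aff <- matrix(rgamma(n * h, shape = config$affinity_concentration),
                nrow = n)
  aff <- aff / rowSums(aff)
  rownames(aff) <- taxa
  habitats <- sim_habitat_table(h)
  colnames(aff) <- habitats$l3

  layers <- c("herb", "shrub", "tree")
  home <- sample(layers, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  names(home) <- taxa
  two_layer <- runif(n) < config$two_layer_fraction
  names(two_layer) <- taxa

  structure(
    list(taxa = taxa, traits = traits, phylogeny = tree,
         attributes = attributes, affinity = aff, home_layer = home,
         two_layer = two_layer, habitats = habitats),
    class = "rsv_species_pool"
  )
}

# choose initial and final habitat rows consistent with a trajectory
sim_pick_habitats <- function(trajectory, habitats) {
  chain <- habitats[habitats$group == "terrestrial", , drop = FALSE]
  chain <- chain[order(chain$rank), , drop = FALSE]
  pick <- function(rows) rows[sample(nrow(rows), 1L), , drop = FALSE]
  if (trajectory == "succession" || trajectory == "disturbance") {
    if (nrow(chain) < 2L) {
      stop("succession/disturbance trajectories need >= 2 chain habitats")
    }
    if (trajectory == "succession") {
      h1 <- pick(chain[-nrow(chain), , drop = FALSE])
      h2 <- chain[match(h1$rank, chain$rank) + 1L, , drop = FALSE]
    } else {
      h1 <- pick(chain[-1L, , drop = FALSE])
      h2 <- chain[match(h1$rank, chain$rank) - 1L, , drop = FALSE]
    }
    return(list(h1 = h1, h2 = h2))
  }
  if (trajectory == "other") {
    # undirected shift: cross between the terrestrial chain and an
    # off-chain habitat group, so the rank fallback yields "other"
    off_chain <- habitats[habitats$group != "terrestrial", , drop = FALSE]
    if (nrow(off_chain) && nrow(chain)) {
      if (runif(1) < 0.5) {
        return(list(h1 = pick(chain), h2 = pick(off_chain)))
      }
      return(list(h1 = pick(off_chain), h2 = pick(chain)))
    }
  }
  h1 <- pick(habitats)
  list(h1 = h1, h2 = h1)
}

#' Simulate a resurvey dataset with known ground truth
#'
#' Each series draws a trajectory, habitat(s), observation count, span, and
#' start year; the initial community samples species proportionally to
#' their affinity for the series habitat with lognormal baseline covers.
#' At later observations the expected richness follows
#' \eqn{S_0 e^{rt}} (stochastic rounding, so the target is unbiased),
#' per-species covers are multiplied by \eqn{e^{ct}} with lognormal noise
#' and capped at 100, and a Poisson number of equal-rate composition swaps
#' applies turnover. Successional, disturbance, and undirected series
#' switch habitat pool and EUNIS codes at the series midpoint;
#' unclassifiable series carry no level-3 code.
#'
#' @param pool a [generate_pool()] result.
#' @param config the same [sim_config()].
#' @return list with `dataset` (an `rsv_dataset`) and `truth` (list with
#'   `series` and `species` ground-truth tables).
#' @export
simulate_dataset <- function(pool, config) {
  stopifnot(inherits(pool, "rsv_species_pool"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  habitats <- pool$habitats
  taxa <- pool$taxa
  n_sp <- length(taxa)
  r <- config$richness_log_trend
  cg <- config$cover_log_trend
  plot_size_by_l1 <- c(V = 16, R = 16, S = 50, T = 200, Q = 25, P = 25,
                       U = 16, N = 25)

  col_names <- c("obs_id", "series_id", "plot_id", "year", "plot_size",
                 "taxon", "layer", "cover", "eunis_l1", "eunis_l3",
                 "design", "manipulated")
  acc <- setNames(lapply(col_names, function(nm) list()), col_names)
  push <- function(rows) {
    for (nm in names(acc)) acc[[nm]][[length(acc[[nm]]) + 1L]] <<- rows[[nm]]
  }

  truth_series <- vector("list", config$n_series)
  capped_warn <- FALSE
  layers_next <- c(herb = "shrub", shrub = "tree", tree = "herb")

  for (i in seq_len(config$n_series)) {
    sid <- sprintf("S%05d", i)
    trajectory <- sample(names(config$trajectory_mix), 1L,
                         prob = config$trajectory_mix)
    hb <- sim_pick_habitats(trajectory, habitats)
    n_obs <- as.integer(sample(names(config$obs_per_series_probs), 1L,
                               prob = config$obs_per_series_probs))
    cls <- config$span_classes[sample(nrow(config$span_classes), 1L,
                                      prob = config$span_classes$p), ]
    spans <- seq.int(cls$lo, cls$hi)
    span <- spans[sample.int(length(spans), 1L)]
    n_obs <- min(n_obs, span + 1L)
    starts <- seq.int(config$year_min, config$year_max - span)
    y0 <- starts[sample.int(length(starts), 1L)]
    years <- c(y0, y0 + span)
    if (n_obs > 2L) {
      interior <- seq.int(y0 + 1L, y0 + span - 1L)
      years <- sort(c(years, interior[sample.int(length(interior),
                                                 n_obs - 2L)]))
    }
    mid <- y0 + span / 2
    design <- if (runif(1) < config$p_semi_permanent) "semi_permanent" else "permanent"
    psize <- unname(plot_size_by_l1[hb$h1$l1])
    size_change <- runif(1) < config$p_size_change

    s0 <- min(n_sp, 1L + rpois(1L, max(0, config$mean_initial_richness - 1)))
    members <- sample(taxa, s0, prob = pool$affinity[, hb$h1$l3])
    base <- rlnorm(s0, config$cover_meanlog, config$cover_sdlog)
    names(base) <- members

    prev_year <- y0
    for (j in seq_along(years)) {
      t_j <- years[j] - y0
      hab <- if (years[j] >= mid && j > 1L) hb$h2 else hb$h1
      aff <- pool$affinity[, hab$l3]

      if (j > 1L) {
        # turnover: equal-rate swaps keep richness and turnover orthogonal
        n_swap <- rpois(1L, config$turnover_rate * (years[j] - prev_year))
        for (sw in seq_len(n_swap)) {
          if (length(members) < 2L || length(members) >= n_sp) break
          out_sp <- sample(members, 1L)
          cand <- setdiff(taxa, members)
          in_sp <- cand[sample.int(length(cand), 1L, prob = aff[cand])]
          members <- c(setdiff(members, out_sp), in_sp)
          base[in_sp] <- rlnorm(1L, config$cover_meanlog, config$cover_sdlog) /
            exp(cg * t_j)
        }
        # richness target: stochastic rounding of S0 * exp(r t)
        x <- s0 * exp(r * t_j)
        target <- floor(x)
        frac <- x - target
        if (frac > 0) target <- target + (runif(1) < frac)
        target <- max(1L, as.integer(target))
        if (target > n_sp) {
          target <- n_sp
          if (!capped_warn) {
            warning("richness target exceeded pool size; capped")
            capped_warn <- TRUE
          }
        }
        while (length(members) < target) {
          cand <- setdiff(taxa, members)
          in_sp <- cand[sample.int(length(cand), 1L, prob = aff[cand])]
          members <- c(members, in_sp)
          base[in_sp] <- rlnorm(1L, config$cover_meanlog, config$cover_sdlog) /
            exp(cg * t_j)
        }
        while (length(members) > target) {
          members <- setdiff(members, sample(members, 1L))
        }
      }

      eps <- rnorm(length(members), 0, config$cover_noise_sd)
      covers <- pmin(100, base[members] * exp(cg * t_j) * exp(eps))
      obs_id <- sprintf("%s_o%02d", sid, j)
      two <- pool$two_layer[members]
      home <- pool$home_layer[members]
      tax_rows <- c(members, members[two])
      lay_rows <- c(home, unname(layers_next[home[two]]))
      # split two-layer covers so the overlap combination returns the target
      split_cov <- 100 * (1 - sqrt(1 - covers / 100))
      cov_rows <- c(ifelse(two, split_cov, covers), split_cov[two])
      sz <- if (size_change && j == length(years)) psize * 3 else psize
      push(list(
        obs_id = rep(obs_id, length(tax_rows)),
        series_id = rep(sid, length(tax_rows)),
        plot_id = rep(sid, length(tax_rows)),
        year = rep(years[j], length(tax_rows)),
        plot_size = rep(sz, length(tax_rows)),
        taxon = tax_rows, layer = unname(lay_rows), cover = unname(cov_rows),
        eunis_l1 = rep(hab$l1, length(tax_rows)),
        eunis_l3 = rep(if (trajectory == "unclassifiable") NA_character_ else hab$l3,
                       length(tax_rows)),
        design = rep(design, length(tax_rows)),
        manipulated = rep(runif(1) < config$p_manipulated, length(tax_rows))
      ))
      prev_year <- years[j]
    }
    truth_series[[i]] <- data.frame(
      series_id = sid, trajectory = trajectory,
      habitat1_l3 = hb$h1$l3, habitat2_l3 = hb$h2$l3,
      n_obs = length(years), span = span, first_year = y0,
      stringsAsFactors = FALSE
    )
  }

  comm <- as.data.frame(lapply(acc, function(col) unlist(col, use.names = FALSE)),
                        stringsAsFactors = FALSE)
  ds <- rsv_dataset(comm, traits = pool$traits, phylogeny = pool$phylogeny,
                    attributes = pool$attributes)
  breadth <- 1 / (ncol(pool$affinity) * rowSums(pool$affinity^2))
  truth <- list(
    series = do.call(rbind, truth_series),
    species = data.frame(taxon = taxa, affinity_breadth = unname(breadth),
                         stringsAsFactors = FALSE),
    pct_per_year = c(richness = (exp(r) - 1) * 100,
                     cover = (exp(cg) - 1) * 100)
  )
  list(dataset = ds, truth = truth)
}
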