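#' Exact convex-hull volume of a small point set in any dimension
#'
#' Facet-enumeration algorithm suited to community-sized point sets: every
#' d-subset of points is tested as a supporting hyperplane; the hull volume
#' is assembled as the sum of cones from the centroid over the facets, each
#' facet's (d-1)-measure computed recursively in an orthonormal basis of its
#' hyperplane. Exact for points in general or degenerate-facet position;
#' points spanning fewer than d dimensions yield a degenerate result.
#'
#' @param pts numeric matrix, one point per row.
#' @return list with `volume` (NA when degenerate), `vertices` (row indices
#'   of hull vertices), and `degenerate` flag.
#' @export
convhull_volume <- function(pts) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  n <- nrow(pts); d <- ncol(pts)
  if (n < d + 1L) return(list(volume = NA_real_, vertices = integer(0),
                              degenerate = TRUE))
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2L, ctr)
  scale0 <- max(abs(cpts), 1e-12)
  if (qr(cpts)$rank < d) {
    return(list(volume = NA_real_, vertices = integer(0), degenerate = TRUE))
  }
  if (d == 1L) {
    return(list(volume = max(pts[, 1L]) - min(pts[, 1L]),
                vertices = unique(c(which.min(pts[, 1L]), which.max(pts[, 1L]))),
                degenerate = FALSE))
  }
  tol <- 1e-9 * scale0
  combos <- combn(n, d)
  nc <- ncol(combos)
  # hyperplane normals for every d-subset at once, via the generalized
  # cross product of the d-1 edge vectors (cofactor expansion), hand-coded
  # for d <= 4; each is an nc x d matrix operation
  p1 <- pts[combos[1L, ], , drop = FALSE]
  edges <- lapply(seq_len(d - 1L), function(j) {
    pts[combos[j + 1L, ], , drop = FALSE] - p1
  })
  nrm <- if (d == 2L) {
    u <- edges[[1L]]
    cbind(-u[, 2L], u[, 1L])
  } else if (d == 3L) {
    u <- edges[[1L]]; v <- edges[[2L]]
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  } else if (d == 4L) {
    u <- edges[[1L]]; v <- edges[[2L]]; w <- edges[[3L]]
    d3 <- function(c1, c2, c3) {
      u[, c1] * (v[, c2] * w[, c3] - v[, c3] * w[, c2]) -
      u[, c2] * (v[, c1] * w[, c3] - v[, c3] * w[, c1]) +
      u[, c3] * (v[, c1] * w[, c2] - v[, c2] * w[, c1])
    }
    cbind(d3(2L, 3L, 4L), -d3(1L, 3L, 4L), d3(1L, 2L, 4L), -d3(1L, 2L, 3L))
  } else {
    t(vapply(seq_len(nc), function(k) {
      a <- do.call(rbind, lapply(edges, function(e) e[k, ]))
      vapply(seq_len(d), function(i) {
        (-1)^(i + 1L) * det(a[, -i, drop = FALSE])
      }, 0)
    }, numeric(d)))
  }
  nn <- sqrt(rowSums(nrm^2))
  ok <- is.finite(nn) & nn > 1e-12 * scale0^(d - 1L)
  nrm <- nrm / pmax(nn, .Machine$double.xmin)
  offset <- rowSums(nrm * p1)
  side <- nrm %*% t(pts) - offset                   # nc x n signed distances
  below <- rowSums(side > tol) == 0L
  above <- rowSums(side < -tol) == 0L
  supporting <- which(ok & (below | above))

  facets <- new.env(parent = emptyenv())
  for (k in supporting) {
    on_pl <- which(abs(side[k, ]) <= tol)
    key <- paste(on_pl, collapse = ",")
    if (is.null(facets[[key]])) {
      facets[[key]] <- list(idx = on_pl, normal = nrm[k, ],
                            offset = offset[k])
    }
  }
  fkeys <- ls(facets)
  if (!length(fkeys)) {
    return(list(volume = NA_real_, vertices = integer(0), degenerate = TRUE))
  }
  vol <- 0
  verts <- integer(0)
  for (key in fkeys) {
    f <- facets[[key]]
    fp <- pts[f$idx, , drop = FALSE]
    h <- abs(sum(f$normal * ctr) - f$offset)
    if (length(f$idx) == d) {
      # simplex facet: (d-1)-measure from the Gram determinant of its edges
      e <- fp[-1L, , drop = FALSE] - matrix(fp[1L, ], d - 1L, d, byrow = TRUE)
      g <- det(tcrossprod(e))
      if (g <= 0) next
      measure <- sqrt(g) / factorial(d - 1L)
      fverts <- f$idx
    } else {
      # coplanar facet: recurse on its projection into the hyperplane
      basis <- qr.Q(qr(cbind(f$normal, diag(d))))[, 2:d, drop = FALSE]
      proj <- sweep(fp, 2L, fp[1L, ]) %*% basis
      sub <- convhull_volume(proj)
      if (is.na(sub$volume)) next
      measure <- sub$volume
      fverts <- f$idx[sub$vertices]
    }
    vol <- vol + measure * h / d
    verts <- union(verts, fverts)
  }
  # hull vertices: points appearing as vertices of at least one facet
  list(volume = vol, vertices = sort(verts), degenerate = FALSE)
}
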