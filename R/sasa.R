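#' Deterministic Fibonacci-sphere quadrature points
#'
#' Near-uniform point set on the unit sphere; no RNG involved, so every
#' SASA value is bit-reproducible for a given `n`.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over van der Waals spheres: for each query atom,
#' quadrature points on its expanded sphere (radius + probe) count as
#' accessible when outside every other atom's expanded sphere. Returns the
#' per-atom SASA of the query atoms, computed in the context of all atoms
#' supplied (context atoms can bury query atoms without contributing area).
#'
#' @param xyz n x 3 coordinate matrix of all context atoms (Angstrom).
#' @param elements length-n element symbols for radius lookup.
#' @param query indices of atoms whose SASA to compute (default all).
#' @param probe probe radius, Angstrom.
#' @param n_points quadrature points per atom (>= 92).
#' @param points optional explicit unit-sphere point set (overrides
#'   `n_points`); used by independent-oracle tests.
#' @return numeric vector of per-atom SASA (Angstrom^2) for `query`.
#' @export
sasa_shrake_rupley <- function(xyz, elements, query = seq_len(nrow(xyz)),
                               probe = 1.4, n_points = 960, points = NULL) {
  if (is.null(points)) {
    if (n_points < 92) stop("n_points must be >= 92")
    points <- fibonacci_sphere(n_points)
  }
  np <- nrow(points)
  xyz <- as.matrix(xyz)
  radii <- vdw_radii()
  el <- toupper(elements)
  unknown <- !(el %in% names(radii))
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; using carbon radius 1.70")
    el[unknown] <- "C"
  }
  r <- radii[el] + probe
  out <- numeric(length(query))
  for (k in seq_along(query)) {
    i <- query[k]
    ri <- r[i]
    pts <- points * ri + matrix(xyz[i, ], np, 3, byrow = TRUE)
    # neighbours whose expanded sphere can reach atom i's expanded sphere
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + r)^2 & seq_along(d2) != i)
    acc <- rep(TRUE, np)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
             (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 > r[j]^2
    }
    out[k] <- 4 * pi * ri^2 * sum(acc) / np
  }
  out
}
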