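# Incremental 3D convex hull.
#
# Small point sets (a binding pocket has on the order of 10^2 heavy atoms),
# so an O(n * f) incremental construction is ample. Faces are triangles
# stored as vertex-index triples oriented so normals point away from an
# interior reference point.

#' Convex hull volume and surface area of a 3D point set
#'
#' @param pts numeric matrix (n x 3) of point coordinates.
#' @param tol degeneracy tolerance, relative to the point-cloud scale.
#' @return list with `volume`, `area`, and `faces` (m x 3 index matrix).
#' @export
convex_hull3 <- function(pts, tol = 1e-10) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3)
  n <- nrow(pts)
  if (n < 4) stop("convex hull requires >= 4 points, got ", n)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  eps <- tol * scale

  init <- initial_tetrahedron(pts, eps)
  interior <- colMeans(pts[init, , drop = FALSE])

  orient <- function(tri) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
    nrm <- cross3(b - a, c - a)
    if (sum(nrm * (a - interior)) < 0) tri[c(1, 3, 2)] else tri
  }
  faces <- rbind(orient(init[c(1, 2, 3)]), orient(init[c(1, 2, 4)]),
                 orient(init[c(1, 3, 4)]), orient(init[c(2, 3, 4)]))

  face_normal <- function(tri) {
    a <- pts[tri[1], ]
    nrm <- cross3(pts[tri[2], ] - a, pts[tri[3], ] - a)
    list(n = nrm, a = a)
  }

  for (p in setdiff(seq_len(n), init)) {
    vis <- vapply(seq_len(nrow(faces)), function(f) {
      fn <- face_normal(faces[f, ])
      sum(fn$n * (pts[p, ] - fn$a)) > eps * sqrt(sum(fn$n^2))
    }, logical(1))
    if (!any(vis)) next
    # horizon = undirected edges used by exactly one visible face
    vf <- faces[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    newf <- t(apply(horizon, 1, function(e) orient(c(e[1], e[2], p))))
    faces <- rbind(faces, newf)
  }

  vol <- 0; area <- 0
  for (f in seq_len(nrow(faces))) {
    a <- pts[faces[f, 1], ]; b <- pts[faces[f, 2], ]; c <- pts[faces[f, 3], ]
    nrm <- cross3(b - a, c - a)
    area <- area + sqrt(sum(nrm^2)) / 2
    vol <- vol + sum(cross3(b - interior, c - interior) * (a - interior)) / 6
  }
  list(volume = abs(vol), area = area, faces = faces)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# four affinely independent points, or a degenerate-geometry error
initial_tetrahedron <- function(pts, eps) {
  n <- nrow(pts)
  i1 <- 1
  d <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d)
  if (sqrt(d[i2]) <= eps) stop("degenerate point set: all points coincide")
  ab <- pts[i2, ] - pts[i1, ]
  # farthest from the line i1-i2
  t <- as.vector((sweep(pts, 2, pts[i1, ]) %*% ab) / sum(ab^2))
  perp <- pts - (outer(t, ab) + matrix(pts[i1, ], n, 3, byrow = TRUE))
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) <= eps) {
    stop("degenerate point set: points are collinear")
  }
  nrm <- cross3(ab, pts[i3, ] - pts[i1, ])
  h <- abs(as.vector(sweep(pts, 2, pts[i1, ]) %*% nrm)) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] <= eps) stop("degenerate point set: points are coplanar")
  c(i1, i2, i3, i4)
}
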