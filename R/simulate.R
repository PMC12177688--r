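#' Simulate a TCSPC decay histogram
#'
#' Draws photon arrival times from a wrapped (periodic) multi-exponential
#' mixture on `[0, T)`: an exponential arrival time taken modulo the laser
#' period, which is exactly the distribution a TCSPC experiment measures
#' when the excited-state population has not fully decayed between pulses.
#' Optionally convolves with a Gaussian instrument response (mod T) before
#' binning.
#'
#' @param components data.frame with columns `tau` (ns) and `fraction`
#'   (summing to 1), or a single lifetime.
#' @param n_photons total photon count (> 0); the histogram sums to this.
#' @param n_bins number of uniform bins over `[0, period]`.
#' @param period laser repetition period T, ns.
#' @param irf_sigma Gaussian IRF standard deviation, ns, or `NULL` for an
#'   ideal instrument.
#' @param seed RNG seed; identical seeds give identical histograms.
#' @return A [decay_histogram()].
#' @export
simulate_decay <- function(components, n_photons, n_bins = 256, period = 25,
                           irf_sigma = NULL, seed = NULL) {
  if (is.numeric(components) && is.null(dim(components))) {
    components <- data.frame(tau = components,
                             fraction = rep(1 / length(components),
                                            length(components)))
  }
  stopifnot(all(c("tau", "fraction") %in% names(components)))
  if (any(components$tau <= 0)) stop("component lifetimes must be > 0")
  if (any(components$fraction < 0) ||
      abs(sum(components$fraction) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1")
  }
  if (n_photons <= 0) stop("n_photons must be > 0")
  if (!is.null(seed)) set.seed(seed)
  active <- which(components$fraction > 0)
  if (length(active) == 1) {
    comp <- rep(active, n_photons)
  } else {
    comp <- sample(active, n_photons, replace = TRUE,
                   prob = components$fraction[active])
  }
  times <- stats::rexp(n_photons) * components$tau[comp]
  if (!is.null(irf_sigma) && irf_sigma > 0) {
    times <- times + stats::rnorm(n_photons, 0, irf_sigma)
  }
  times <- times %% period
  counts <- tabulate(pmin(floor(times / (period / n_bins)) + 1L, n_bins),
                     nbins = n_bins)
  decay_histogram(counts, period)
}

#' Noiseless expected decay histogram
#'
#' Exact binned expectation of the wrapped multi-exponential mixture (no
#' Poisson noise, no sampling), useful as a noiseless reference decay and
#' for identity tests of the unmixing chain.
#'
#' @inheritParams simulate_decay
#' @param total total intensity the expectation is scaled to.
#' @return A [decay_histogram()] with non-integer counts.
#' @export
expected_decay <- function(components, total = 1, n_bins = 256, period = 25) {
  if (is.numeric(components) && is.null(dim(components))) {
    components <- data.frame(tau = components,
                             fraction = rep(1 / length(components),
                                            length(components)))
  }
  edges <- seq(0, period, length.out = n_bins + 1)
  e0 <- utils::head(edges, -1); e1 <- utils::tail(edges, -1)
  p <- numeric(n_bins)
  for (i in seq_len(nrow(components))) {
    tau <- components$tau[i]
    pi_ <- (exp(-e0 / tau) - exp(-e1 / tau)) / (1 - exp(-period / tau))
    p <- p + components$fraction[i] * pi_
  }
  decay_histogram(p / sum(p) * total, period, edges)
}

# ---- FLIM scene simulation ----------------------------------------------

#' Elliptical, ring and scattered-dot region masks
#'
#' Mask generators for synthetic FLIM scenes, mimicking a nucleus, a
#' perinuclear Golgi ring, and scattered mitochondria/vesicle puncta.
#'
#' @param size image size `c(Y, X)`.
#' @param center ellipse/ring center (y, x), pixels.
#' @param radii ellipse semi-axes (y, x), pixels.
#' @return logical Y x X matrix.
#' @export
region_ellipse <- function(size, center, radii) {
  y <- matrix(seq_len(size[1]), size[1], size[2])
  x <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((y - center[1]) / radii[1])^2 + ((x - center[2]) / radii[2])^2 <= 1
}

#' @rdname region_ellipse
#' @param inner,outer inner and outer semi-axes (y, x) of the ring.
#' @export
region_ring <- function(size, center, inner, outer) {
  region_ellipse(size, center, outer) & !region_ellipse(size, center, inner)
}

#' @rdname region_ellipse
#' @param n_dots number of puncta.
#' @param dot_radius punctum radius, pixels.
#' @param exclude optional logical mask where dots may not be seeded.
#' @return logical Y x X matrix.
#' @export
region_dots <- function(size, n_dots, dot_radius = 2, exclude = NULL) {
  mask <- matrix(FALSE, size[1], size[2])
  centers_y <- sample.int(size[1], n_dots, replace = TRUE)
  centers_x <- sample.int(size[2], n_dots, replace = TRUE)
  if (!is.null(exclude)) {
    ok <- !exclude[cbind(centers_y, centers_x)]
    centers_y <- centers_y[ok]; centers_x <- centers_x[ok]
  }
  for (i in seq_along(centers_y)) {
    mask <- mask | region_ellipse(size, c(centers_y[i], centers_x[i]),
                                  c(dot_radius, dot_radius))
  }
  mask
}

#' Default three-organelle FLIM scene specification
#'
#' A scene with the geometry of a two-tag co-expression experiment: an
#' elliptical nucleus, a perinuclear ring standing in for the Golgi
#' apparatus, and scattered puncta for mitochondria/vesicles where unbound
#' dye accumulates. Default component lifetimes are the measured values
#' for the dye bound to the two HaloTag mutants (5.9 and 5.5 ns) and free
#' in cells (1.4 ns).
#'
#' The default photon budget (10^4 photons/pixel) reflects the accumulated
#' TCSPC stacks used for lifetime unmixing: discriminating species 0.4 ns
#' apart at a 25 ns period separates their phasors by about 0.033, while
#' the phasor shot-noise radius is roughly `0.5/sqrt(N)`, so reliable
#' per-pixel assignment of the two protein-bound species requires a few
#' thousand photons per pixel.
#'
#' @param size image size `c(Y, X)`.
#' @param mean_photons mean photons per pixel inside each region.
#' @param components data.frame `name`, `tau` (one row per species).
#' @param period laser period, ns.
#' @param n_bins time bins.
#' @param seed RNG seed for mask placement and photon noise.
#' @return A scene specification list for [simulate_flim_image()].
#' @export
flim_scene <- function(size = c(64, 64), mean_photons = 10000,
                       components = data.frame(
                         name = c("golgi", "nucleus", "mito"),
                         tau = c(5.9, 5.5, 1.4)),
                       period = 25, n_bins = 256, seed = 1) {
  stopifnot(all(components$tau > 0))
  cy <- size[1] / 2; cx <- size[2] / 2
  ry <- size[1] * 0.18; rx <- size[2] * 0.22
  list(size = size, components = components, period = period,
       n_bins = n_bins, seed = seed,
       regions = list(
         list(generator = "ring", component = 1, mean_photons = mean_photons,
              center = c(cy, cx), inner = c(ry * 1.2, rx * 1.2),
              outer = c(ry * 1.7, rx * 1.7)),
         list(generator = "ellipse", component = 2,
              mean_photons = mean_photons,
              center = c(cy, cx), radii = c(ry, rx)),
         list(generator = "dots", component = 3, mean_photons = mean_photons,
              n_dots = max(6, round(prod(size) / 680)), dot_radius = 2)))
}

build_mask <- function(region, size, exclude) {
  switch(region$generator,
    ellipse = region_ellipse(size, region$center, region$radii),
    ring = region_ring(size, region$center, region$inner, region$outer),
    dots = region_dots(size, region$n_dots, region$dot_radius,
                       exclude = exclude),
    stop("unknown region generator: ", region$generator))
}

#' Simulate a time-resolved FLIM image stack with known ground truth
#'
#' Each region contributes Poisson photons at its mean rate to its pixels;
#' arrival times follow the wrapped exponential of the region's component.
#' Overlapping regions mix in proportion to their photon budgets. Ground
#' truth (expected per-component fractions and majority component per
#' pixel) is returned alongside the stack.
#'
#' @param scene scene specification from [flim_scene()] (or a compatible
#'   list).
#' @param irf_sigma optional Gaussian IRF sd, ns.
#' @return list with `stack` (array `n_bins` x Y x X), `truth` (list
#'   `fractions` array (Y, X, n_comp), `majority` Y x X integer matrix, 0
#'   where no photons are expected, `expected_photons` Y x X), `scene`.
#' @export
simulate_flim_image <- function(scene, irf_sigma = NULL) {
  size <- scene$size
  ncomp <- nrow(scene$components)
  if (length(scene$regions) == 0) stop("scene has no regions")
  set.seed(scene$seed)
  nb <- scene$n_bins; T <- scene$period
  npx <- prod(size)
  stack_vec <- numeric(nb * npx)
  expected <- array(0, c(size[1], size[2], ncomp))
  occupied <- matrix(FALSE, size[1], size[2])
  masks <- list()
  for (r in seq_along(scene$regions)) {
    reg <- scene$regions[[r]]
    m <- build_mask(reg, size, exclude = occupied)
    masks[[r]] <- m
    occupied <- occupied | m
    expected[, , reg$component] <- expected[, , reg$component] +
      reg$mean_photons * m
  }
  if (sum(expected) == 0) stop("scene generates zero expected photons")
  for (r in seq_along(scene$regions)) {
    reg <- scene$regions[[r]]
    px <- which(masks[[r]])           # linear pixel indices
    if (!length(px)) next
    nph <- stats::rpois(length(px), reg$mean_photons)
    tot <- sum(nph)
    if (tot == 0) next
    tau <- scene$components$tau[reg$component]
    times <- stats::rexp(tot) * tau
    if (!is.null(irf_sigma) && irf_sigma > 0) {
      times <- times + stats::rnorm(tot, 0, irf_sigma)
    }
    times <- times %% T
    bin <- pmin(floor(times / (T / nb)) + 1L, nb)
    pix <- rep(px, nph)
    lin <- (pix - 1L) * nb + bin
    stack_vec <- stack_vec + tabulate(lin, nbins = nb * npx)
  }
  stack <- array(stack_vec, c(nb, size[1], size[2]))
  tot_exp <- apply(expected, c(1, 2), sum)
  frac <- expected
  for (j in seq_len(ncomp)) {
    frac[, , j] <- ifelse(tot_exp > 0, expected[, , j] / tot_exp, 0)
  }
  majority <- apply(expected, c(1, 2), which.max)
  majority[tot_exp == 0] <- 0L
  list(stack = stack,
       truth = list(fractions = frac, majority = majority,
                    expected_photons = tot_exp),
       scene = scene)
}

# ---- synthetic structure sets -------------------------------------------

# minimal heavy-atom residue templates (local coordinates, anchor = CA at
# origin, side chain along +x); geometry is schematic, not physical -- it
# only needs to give valid PDB records, correct atom names for charge and
# hydropathy lookups, and a 3D spread for hull metrics
residue_templates <- function() {
  bb <- function(...) {
    sc <- rbind(...)
    rbind(data.frame(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
                     x = c(-1.2, 0, 1.0, 1.4), y = c(0.8, 0, 1.0, 2.1),
                     z = c(0, 0, -0.6, -0.6)),
          sc)
  }
  a <- function(name, element, x, y, z) {
    data.frame(name = name, element = element, x = x, y = y, z = z)
  }
  list(
    GLY = bb(),
    ALA = bb(a("CB", "C", 1.0, -1.0, 0.9)),
    VAL = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG1", "C", 2.3, -0.8, 1.6),
             a("CG2", "C", 0.6, -2.3, 1.5)),
    LEU = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("CD1", "C", 3.3, -1.9, 0.9), a("CD2", "C", 2.0, -2.4, 2.7)),
    ILE = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG1", "C", 2.3, -1.0, 1.6),
             a("CG2", "C", 0.5, -2.3, 0.4), a("CD1", "C", 3.3, -1.9, 1.0)),
    SER = bb(a("CB", "C", 1.0, -1.0, 0.9), a("OG", "O", 2.2, -0.9, 1.6)),
    THR = bb(a("CB", "C", 1.0, -1.0, 0.9), a("OG1", "O", 2.2, -0.8, 1.6),
             a("CG2", "C", 0.5, -2.3, 1.3)),
    MET = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("SD", "S", 3.5, -2.0, 1.0), a("CE", "C", 4.6, -2.2, 2.3)),
    PHE = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("CD1", "C", 3.4, -0.7, 1.5), a("CD2", "C", 2.2, -2.3, 2.6),
             a("CE1", "C", 4.5, -1.0, 2.3), a("CE2", "C", 3.3, -2.6, 3.4),
             a("CZ", "C", 4.5, -2.0, 3.2)),
    ASN = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("OD1", "O", 3.2, -0.6, 1.8), a("ND2", "N", 2.2, -2.4, 2.4)),
    GLN = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("CD", "C", 3.4, -1.8, 0.9), a("OE1", "O", 4.4, -1.2, 0.9),
             a("NE2", "N", 3.4, -2.9, 0.3)),
    ASP = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("OD1", "O", 3.2, -0.6, 1.8), a("OD2", "O", 2.2, -2.4, 2.3)),
    GLU = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("CD", "C", 3.4, -1.8, 0.9), a("OE1", "O", 4.4, -1.2, 0.9),
             a("OE2", "O", 3.4, -2.9, 0.3)),
    LYS = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("CD", "C", 3.4, -1.8, 0.9), a("CE", "C", 4.6, -2.2, 1.7),
             a("NZ", "N", 5.8, -2.7, 1.0)),
    ARG = bb(a("CB", "C", 1.0, -1.0, 0.9), a("CG", "C", 2.2, -1.3, 1.7),
             a("CD", "C", 3.4, -1.8, 0.9), a("NE", "N", 4.6, -2.2, 1.6),
             a("CZ", "C", 5.8, -2.6, 1.0), a("NH1", "N", 6.9, -3.0, 1.7),
             a("NH2", "N", 5.9, -2.7, -0.3))
  )
}

# fixed schematic dye: a hexagonal ring with two substituents, hetero
# residue LIG; heavy atoms only
ligand_template <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  df <- data.frame(name = paste0("C", 1:6), element = "C",
                   x = 1.4 * cos(ang), y = 1.4 * sin(ang), z = 0)
  rbind(df,
        data.frame(name = "N1", element = "N", x = 2.8, y = 0, z = 0.2),
        data.frame(name = "O1", element = "O", x = -2.8, y = 0, z = -0.2))
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  # QR of a Gaussian matrix gives a Haar-ish rotation; fix determinant +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Specification for a synthetic structure set
#'
#' @param n_proteins number of pseudo-proteins (>= 3).
#' @param n_models predicted models per protein.
#' @param n_pocket_residues residues in the 5-Angstrom shell around the dye.
#' @param n_distal_residues residues placed well outside the shell (so
#'   pocket extraction is a strict subset).
#' @param dipole_range range (e*Angstrom) the per-protein target pocket
#'   dipole magnitude is drawn from uniformly.
#' @param lifetime_a,lifetime_b,lifetime_sd the lifetime law
#'   `tau = a + b * |mu| + N(0, sd)` (ns); `b` must be negative.
#' @param jitter per-model coordinate jitter sd, Angstrom.
#' @param seed RNG seed.
#' @return Specification list for [simulate_structure_set()].
#' @export
structure_set_spec <- function(n_proteins = 12, n_models = 10,
                               n_pocket_residues = 12,
                               n_distal_residues = 4,
                               dipole_range = c(1, 8),
                               lifetime_a = 6.0, lifetime_b = -0.45,
                               lifetime_sd = 0.15,
                               jitter = 0.15, seed = 1) {
  if (n_proteins < 3) stop("n_proteins must be >= 3")
  if (lifetime_b >= 0) stop("lifetime_b must be negative (anticorrelation)")
  if (diff(range(dipole_range)) < 0) stop("invalid dipole_range")
  if (max(dipole_range) > 8.5) {
    stop("infeasible dipole target: charge pair cannot be separated by more ",
         "than ~8.5 Angstrom inside the pocket shell")
  }
  list(n_proteins = n_proteins, n_models = n_models,
       n_pocket_residues = n_pocket_residues,
       n_distal_residues = n_distal_residues,
       dipole_range = dipole_range, lifetime_a = lifetime_a,
       lifetime_b = lifetime_b, lifetime_sd = lifetime_sd,
       jitter = jitter, seed = seed)
}

#' Generate a synthetic protein-ligand structure set with known dipoles
#'
#' Builds pseudo-protein binding pockets around a fixed schematic dye: a
#' shell of amino-acid residues (real residue templates, so hydropathy and
#' charge lookups work unmodified) within 5 Angstrom of the ligand, plus
#' distal residues outside it. One Lys/Asp pair is placed so that under
#' the formal charge scheme the pocket dipole magnitude equals the
#' protein's target exactly (the pocket is net-neutral, so the dipole is
#' origin-independent). Lifetimes follow `tau = a + b|mu| + noise` with
#' `b < 0`. Each model adds independent Gaussian coordinate jitter.
#'
#' @param spec from [structure_set_spec()].
#' @param dir output directory for per-protein multi-model PDB files
#'   (created if needed); `NULL` keeps structures in memory only.
#' @return list with `structures` (named list of `pf_structure`), `paths`
#'   (PDB files, if written), `lifetimes` (data.frame `protein_id`,
#'   `tau_ns`, `source`), `truth` (data.frame `protein_id`,
#'   `dipole_target_eA`).
#' @export
simulate_structure_set <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  tmpl <- residue_templates()
  lig <- ligand_template()
  neutral <- c("ALA", "VAL", "LEU", "ILE", "SER", "THR", "MET", "PHE",
               "ASN", "GLN", "GLY")
  ids <- sprintf("prot%02d", seq_len(spec$n_proteins))
  targets <- stats::runif(spec$n_proteins, spec$dipole_range[1],
                          spec$dipole_range[2])
  structures <- vector("list", spec$n_proteins)
  taus <- numeric(spec$n_proteins)
  paths <- character(0)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  place_residue <- function(resname, anchor_atom, anchor_pos) {
    tp <- tmpl[[resname]]
    xyz <- as.matrix(tp[, c("x", "y", "z")]) %*% t(random_rotation())
    shift <- anchor_pos - xyz[match(anchor_atom, tp$name), ]
    xyz <- sweep(xyz, 2, shift, "+")
    list(df = tp, xyz = xyz)
  }

  for (i in seq_len(spec$n_proteins)) {
    d <- targets[i]
    axis <- random_unit()
    resno <- 0
    atom_rows <- list(); xyz_rows <- list()
    add <- function(resname, anchor_atom, anchor_pos, hetero = FALSE) {
      resno <<- resno + 1
      pr <- place_residue(resname, anchor_atom, anchor_pos)
      atom_rows[[length(atom_rows) + 1]] <<- data.frame(
        name = pr$df$name, element = pr$df$element, resname = resname,
        chain = "A", resno = resno, is_hetero = hetero,
        stringsAsFactors = FALSE)
      xyz_rows[[length(xyz_rows) + 1]] <<- pr$xyz
    }
    # charged pair realising the target dipole exactly (formal scheme)
    add("LYS", "NZ", axis * d / 2)
    add("ASP", "CG", -axis * d / 2)
    n_neutral <- max(0, spec$n_pocket_residues - 2)
    for (k in seq_len(n_neutral)) {
      rn <- sample(neutral, 1)
      anchor <- if (is.null(tmpl[[rn]]$name) || !"CB" %in% tmpl[[rn]]$name)
        "CA" else "CB"
      add(rn, anchor, random_unit() * stats::runif(1, 3.5, 4.5))
    }
    for (k in seq_len(spec$n_distal_residues)) {
      rn <- sample(neutral, 1)
      anchor <- if (!"CB" %in% tmpl[[rn]]$name) "CA" else "CB"
      add(rn, anchor, random_unit() * stats::runif(1, 13, 17))
    }
    # ligand last, as a hetero residue
    resno <- resno + 1
    atom_rows[[length(atom_rows) + 1]] <- data.frame(
      name = lig$name, element = lig$element, resname = "LIG", chain = "A",
      resno = resno, is_hetero = TRUE, stringsAsFactors = FALSE)
    xyz_rows[[length(xyz_rows) + 1]] <- as.matrix(lig[, c("x", "y", "z")])

    atom <- do.call(rbind, atom_rows)
    base_xyz <- do.call(rbind, xyz_rows)
    coords <- lapply(seq_len(spec$n_models), function(m) {
      base_xyz + matrix(stats::rnorm(length(base_xyz), 0, spec$jitter),
                        nrow(base_xyz), 3)
    })
    st <- structure_from_atoms(atom, coords)
    structures[[i]] <- st
    repeat {
      tau <- spec$lifetime_a + spec$lifetime_b * d +
        stats::rnorm(1, 0, spec$lifetime_sd)
      if (tau > 0) break
    }
    taus[i] <- tau
    if (!is.null(dir)) {
      p <- file.path(dir, paste0(ids[i], ".pdb"))
      write_pdb(st, p)
      paths <- c(paths, p)
    }
  }
  names(structures) <- ids
  list(structures = structures, paths = paths,
       lifetimes = data.frame(protein_id = ids, tau_ns = taus,
                              source = "synthetic", stringsAsFactors = FALSE),
       truth = data.frame(protein_id = ids, dipole_target_eA = targets,
                          stringsAsFactors = FALSE))
}
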