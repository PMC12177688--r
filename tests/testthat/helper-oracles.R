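# Independent brute-force oracles and tiny fixture builders.
# Every oracle here is deliberately written as the simplest possible
# computation (double loops, full enumeration) so it shares no code path
# with the package implementation it checks.

# tempfile-per-test helper
withr_local_file <- function(name) {
  file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
}

# build a pf_structure from a list of residues:
# list(list(resname=, resno=, hetero=, atoms=data.frame(name, element, x, y, z)), ...)
toy_structure <- function(residues, chain = "A") {
  atom <- do.call(rbind, lapply(residues, function(r) {
    data.frame(name = r$atoms$name, element = r$atoms$element,
               resname = r$resname, chain = chain, resno = r$resno,
               is_hetero = isTRUE(r$hetero), stringsAsFactors = FALSE)
  }))
  xyz <- do.call(rbind, lapply(residues, function(r) {
    as.matrix(r$atoms[, c("x", "y", "z")])
  }))
  structure_from_atoms(atom, xyz)
}

res_at <- function(resname, resno, xyz, names = NULL, elements = NULL,
                   hetero = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  if (is.null(names)) names <- paste0("C", seq_len(nrow(xyz)))
  if (is.null(elements)) elements <- rep("C", nrow(xyz))
  list(resname = resname, resno = resno, hetero = hetero,
       atoms = data.frame(name = names, element = elements,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# brute-force pocket: O(N*M) all-pairs scan over heavy atoms
bf_pocket_residues <- function(st, model, ligand_resname, cutoff) {
  df <- model_atoms(st, model, heavy_only = TRUE)
  lig <- df[df$resname == ligand_resname, ]
  prot <- df[!df$is_hetero, ]
  keys <- character(0)
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                (prot$z[i] - lig$z[j])^2)
      if (d <= cutoff) keys <- c(keys, paste(prot$chain[i], prot$resno[i]))
    }
  }
  sort(unique(keys))
}

# brute-force convex hull by full face enumeration (general-position input)
bf_hull <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  centroid <- colMeans(pts)
  cr <- function(u, v) c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3],
                         u[1]*v[2] - u[2]*v[1])
  vol <- 0; area <- 0
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
    nrm <- cr(b - a, c - a)
    if (sqrt(sum(nrm^2)) < tol) next
    d <- as.vector((pts - matrix(a, n, 3, byrow = TRUE)) %*% nrm)
    if (all(d <= tol) || all(d >= -tol)) {
      area <- area + sqrt(sum(nrm^2)) / 2
      vol <- vol + abs(sum(cr(b - centroid, c - centroid) * (a - centroid))) / 6
    }
  }
  list(volume = vol, area = area)
}

# hand-rolled Spearman: average ranks, then explicit Pearson formula
bf_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent SASA quadrature: same rolling-probe definition, but a seeded
# random point set (not the Fibonacci lattice) at high resolution
bf_sasa <- function(xyz, elements, query, probe = 1.4, n = 10000, seed = 42) {
  set.seed(seed)
  z <- stats::runif(n, -1, 1)
  th <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  pts <- cbind(r * cos(th), r * sin(th), z)
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  rr <- radii[toupper(elements)] + probe
  out <- numeric(length(query))
  for (k in seq_along(query)) {
    i <- query[k]
    p <- pts * rr[i] + matrix(unlist(xyz[i, ]), n, 3, byrow = TRUE)
    acc <- rep(TRUE, n)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rr[j]^2
    }
    out[k] <- 4 * pi * rr[i]^2 * mean(acc)
  }
  out
}

# a hand-written 3-atom PDB (coordinates chosen to be read back verbatim)
minimal_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "HETATM    3  C1  LIG A   9       0.000   0.000   0.000  1.00  0.00           C",
    "END")
}

# write the same atom table as hand-constructed PDB and mmCIF text; the
# two writers are independent of the package's writer
write_pdb_and_cif <- function(df, pdb_path, cif_path) {
  pdb <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("%s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(df$hetero[i], "HETATM", "ATOM  "), i, df$name[i],
            df$resname[i], df$chain[i], df$resno[i], df$x[i], df$y[i],
            df$z[i], 1, 0, df$element[i])
  }, "")
  writeLines(c(pdb, "END"), pdb_path)
  cif <- c("data_toy", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
           vapply(seq_len(nrow(df)), function(i) {
             sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
                     ifelse(df$hetero[i], "HETATM", "ATOM"), i, df$element[i],
                     df$name[i], df$resname[i], df$chain[i], df$resno[i],
                     df$x[i], df$y[i], df$z[i], df$resno[i], df$resname[i],
                     df$chain[i], df$name[i])
           }, ""))
  writeLines(cif, cif_path)
}

# independent least-squares solve of the 3-component barycentric system
bf_unmix <- function(g, s, refs) {
  M <- rbind(vapply(refs, function(r) r$g, 0),
             vapply(refs, function(r) r$s, 0),
             c(1, 1, 1))
  as.numeric(qr.solve(M, c(g, s, 1)))
}
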