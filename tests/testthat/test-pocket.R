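# a ligand at the origin and two single-atom residues straddling the cutoff
straddle_structure <- function() {
  toy_structure(list(
    res_at("ALA", 1, c(0, 0, 4.9), names = "CA"),
    res_at("GLY", 2, c(0, 0, -5.1), names = "CA"),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
}

test_that("pocket membership follows the 5 A heavy-atom cutoff exactly", {
  st <- straddle_structure()
  pk <- extract_pocket(st, 1, select_ligand(st, "LIG"))
  expect_equal(pk$residues$resname, "ALA")
  expect_equal(nrow(pk$residues), 1)
  # a residue is in if ANY heavy atom is inside the cutoff
  st2 <- toy_structure(list(
    res_at("SER", 1, rbind(c(0, 0, 4.99), c(0, 0, 8)), names = c("CA", "CB")),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk2 <- extract_pocket(st2, 1, select_ligand(st2, "LIG"))
  expect_equal(nrow(pk2$atoms), 2)  # whole residue joins, both atoms
})

test_that("invalid cutoffs and empty pockets are handled", {
  st <- straddle_structure()
  expect_error(extract_pocket(st, 1, select_ligand(st, "LIG"), cutoff = 0),
               "cutoff")
  expect_warning(
    pk <- extract_pocket(st, 1, select_ligand(st, "LIG"), cutoff = 0.5),
    "empty pocket")
  expect_equal(nrow(pk$residues), 0)
  expect_error(pocket_hydropathy(pk), "empty")
  expect_error(pocket_dipole(pk), "empty")
})

test_that("pocket extraction equals the brute-force all-pairs scan", {
  spec <- structure_set_spec(n_proteins = 4, n_models = 3,
                             n_pocket_residues = 12, seed = 11)
  ss <- simulate_structure_set(spec)
  for (st in ss$structures) {
    for (m in seq_len(n_models(st))) {
      pk <- extract_pocket(st, m, select_ligand(st, "LIG", model = m))
      got <- sort(paste(pk$residues$chain, pk$residues$resno))
      expect_equal(got, bf_pocket_residues(st, m, "LIG", 5.0))
    }
  }
})

test_that("growing the cutoff never removes pocket residues", {
  spec <- structure_set_spec(n_proteins = 3, n_models = 1, seed = 21)
  st <- simulate_structure_set(spec)$structures[[1]]
  lig <- select_ligand(st, "LIG")
  prev <- character(0)
  for (cutoff in c(3, 4, 5, 7, 10)) {
    pk <- extract_pocket(st, 1, lig, cutoff = cutoff)
    cur <- paste(pk$residues$chain, pk$residues$resno)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("hydropathy is the unweighted Kyte-Doolittle mean over residues", {
  ile <- toy_structure(list(
    res_at("ILE", 1, c(0, 0, 3), names = "CA"),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk <- extract_pocket(ile, 1, select_ligand(ile, "LIG"))
  expect_equal(pocket_hydropathy(pk), 4.5)

  both <- toy_structure(list(
    res_at("ARG", 1, c(0, 0, 3), names = "CA"),
    res_at("ILE", 2, c(0, 0, -3), names = "CA"),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk2 <- extract_pocket(both, 1, select_ligand(both, "LIG"))
  expect_equal(pocket_hydropathy(pk2), 0.0)  # mean of -4.5 and 4.5
})

test_that("nonstandard residues are skipped for hydropathy, fatal if alone", {
  mixed <- toy_structure(list(
    res_at("ILE", 1, c(0, 0, 3), names = "CA"),
    res_at("MSE", 2, c(0, 3, 0), names = "CA"),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk <- extract_pocket(mixed, 1, select_ligand(mixed, "LIG"))
  expect_warning(h <- pocket_hydropathy(pk), "MSE")
  expect_equal(h, 4.5)

  only_ns <- toy_structure(list(
    res_at("MSE", 1, c(0, 0, 3), names = "CA"),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk2 <- extract_pocket(only_ns, 1, select_ligand(only_ns, "LIG"))
  expect_error(suppressWarnings(pocket_hydropathy(pk2)), "no standard")
})

test_that("formal-scheme dipole matches hand-computed vector sums", {
  # +1 (Lys NZ) at (1,0,0), -1 (Asp CG) at (-1,0,0): |mu| = 2 e*A
  st <- toy_structure(list(
    res_at("LYS", 1, c(1, 0, 0), names = "NZ", elements = "N"),
    res_at("ASP", 2, c(-1, 0, 0), names = "CG"),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk <- extract_pocket(st, 1, select_ligand(st, "LIG"))
  d <- pocket_dipole(pk)
  expect_equal(d$dipole_eA, 2.0, tolerance = 1e-12)
  expect_equal(d$dipole_D, 2.0 * 4.8032, tolerance = 1e-12)
  expect_equal(d$net_charge, 0)
  expect_equal(d$scheme, "formal")

  # centrosymmetric arrangement of equal charges -> zero dipole
  st0 <- toy_structure(list(
    res_at("LYS", 1, c(2, 0, 0), names = "NZ", elements = "N"),
    res_at("LYS", 2, c(-2, 0, 0), names = "NZ", elements = "N"),
    res_at("ASP", 3, c(0, 2, 0), names = "CG"),
    res_at("ASP", 4, c(0, -2, 0), names = "CG"),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk0 <- extract_pocket(st0, 1, select_ligand(st0, "LIG"))
  expect_lt(pocket_dipole(pk0)$dipole_eA, 1e-12)
})

test_that("an 8-atom mixed-charge pocket equals manual arithmetic", {
  # hand-built: Lys NZ +1 at (3,1,0); Arg CZ +1 at (0,3,1);
  # Glu CD -1 at (-3,0,1); plus five neutral carbons
  pos <- rbind(c(3, 1, 0), c(0, 3, 1), c(-3, 0, 1), c(1, 1, 1),
               c(-1, -1, 0), c(2, -2, 1), c(0, 0, -3), c(-2, 2, -1))
  st <- toy_structure(list(
    res_at("LYS", 1, pos[1, ], names = "NZ", elements = "N"),
    res_at("ARG", 2, pos[2, ], names = "CZ"),
    res_at("GLU", 3, pos[3, ], names = "CD"),
    res_at("ALA", 4, pos[4:8, ],
           names = c("CA", "CB", "C", "O", "N"),
           elements = c("C", "C", "C", "O", "N")),
    res_at("LIG", 9, c(0, 0, 0), names = "C1", hetero = TRUE)))
  pk <- extract_pocket(st, 1, select_ligand(st, "LIG"))
  rbar <- colMeans(pos)
  mu <- (pos[1, ] - rbar) + (pos[2, ] - rbar) - (pos[3, ] - rbar)
  d <- pocket_dipole(pk)
  expect_equal(d$dipole_eA, sqrt(sum(mu^2)), tolerance = 1e-12)
  expect_equal(d$net_charge, 1)
})

test_that("dipole is rotation invariant; translation invariant when neutral", {
  spec <- structure_set_spec(n_proteins = 3, n_models = 1, seed = 31)
  st <- simulate_structure_set(spec)$structures[[1]]
  pk <- extract_pocket(st, 1, select_ligand(st, "LIG"))
  d0 <- pocket_dipole(pk)$dipole_eA
  set.seed(2)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- pk
  rot$atoms[, c("x", "y", "z")] <- as.matrix(pk$atoms[, c("x", "y", "z")]) %*% q
  expect_equal(pocket_dipole(rot)$dipole_eA, d0, tolerance = 1e-9)
  shift <- pk
  shift$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(pk$atoms[, c("x", "y", "z")]), 2, c(10, -20, 5), "+")
  expect_equal(pocket_dipole(shift)$dipole_eA, d0, tolerance = 1e-9)
})

test_that("the partial-charge scheme is selectable and recorded", {
  spec <- structure_set_spec(n_proteins = 3, n_models = 1, seed = 41)
  st <- simulate_structure_set(spec)$structures[[1]]
  pk <- extract_pocket(st, 1, select_ligand(st, "LIG"))
  d <- pocket_dipole(pk, "partial_table")
  expect_equal(d$scheme, "partial_table")
  expect_true(is.finite(d$dipole_eA) && d$dipole_eA >= 0)
  expect_false(isTRUE(all.equal(d$dipole_eA,
                                pocket_dipole(pk, "formal")$dipole_eA)))
})

test_that("per-model descriptor tables are deterministic and model-resolved", {
  spec <- structure_set_spec(n_proteins = 3, n_models = 4, jitter = 0,
                             seed = 51)
  st <- simulate_structure_set(spec)$structures[[1]]
  props <- compute_all_properties(st, "LIG", n_points = 92)
  expect_equal(nrow(props), 4)
  for (col in c("volume_A3", "area_A2", "hydropathy", "sasa_A2", "dipole_eA")) {
    expect_true(all(is.finite(props[[col]])))
    expect_equal(stats::sd(props[[col]]), 0)  # identical models, identical rows
  }
  # jittered models differ, and each row equals its own recomputation
  stj <- simulate_structure_set(structure_set_spec(n_proteins = 3,
                                                   n_models = 3, seed = 52))$structures[[1]]
  pj <- compute_all_properties(stj, "LIG", n_points = 92)
  expect_gt(stats::sd(pj$dipole_eA), 0)
  m2 <- 2
  pk2 <- extract_pocket(stj, m2, select_ligand(stj, "LIG", model = m2))
  expect_equal(pj$dipole_eA[m2], pocket_dipole(pk2)$dipole_eA)
  expect_equal(pj$volume_A3[m2], pocket_hull_metrics(pk2)$volume)
  expect_equal(pj$sasa_A2[m2], pocket_sasa(stj, pk2, n_points = 92))
})
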