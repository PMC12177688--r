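#' Extract the ligand-defined binding pocket
#'
#' The pocket is the set of protein residues having at least one heavy atom
#' within `cutoff` Angstrom (heavy-atom center to heavy-atom center) of any
#' ligand heavy atom. The ligand itself is never part of the pocket.
#'
#' @param structure A `pf_structure`.
#' @param model Model index.
#' @param ligand Ligand atoms as returned by [select_ligand()] (for the same
#'   model), or a selector passed through to [select_ligand()].
#' @param cutoff Contact cutoff in Angstrom (default 5.0).
#' @param include_hydrogens Include hydrogens in the distance test and the
#'   pocket atom set? Default `FALSE`: predictor outputs differ in hydrogen
#'   presence, heavy-atom-only keeps pockets comparable across sources.
#' @return Object of class `pf_pocket`: list with `residues` (data.frame
#'   `chain`, `resno`, `insert`, `resname`), `atoms` (pocket atoms with
#'   coordinates), `cutoff`, `model`.
#' @export
extract_pocket <- function(structure, model = 1, ligand, cutoff = 5.0,
                           include_hydrogens = FALSE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!is.data.frame(ligand)) {
    ligand <- select_ligand(structure, ligand, model = model)
  }
  if (!include_hydrogens) ligand <- ligand[ligand$element != "H", , drop = FALSE]
  if (nrow(ligand) == 0) stop("ligand has no (heavy) atoms")
  df <- model_atoms(structure, model, heavy_only = !include_hydrogens)
  prot <- df[!df$is_hetero, , drop = FALSE]
  lig_key <- paste(ligand$chain, ligand$resno, ligand$insert)
  prot <- prot[!(paste(prot$chain, prot$resno, prot$insert) %in% lig_key), ,
               drop = FALSE]
  if (nrow(prot) == 0) {
    warning("no protein atoms; empty pocket")
    return(empty_pocket(cutoff, model))
  }
  lx <- as.matrix(ligand[, c("x", "y", "z")])
  px <- as.matrix(prot[, c("x", "y", "z")])
  # min distance of each protein atom to any ligand atom
  c2 <- cutoff^2
  near <- rep(FALSE, nrow(px))
  for (j in seq_len(nrow(lx))) {
    dz <- (px[, 1] - lx[j, 1])^2 + (px[, 2] - lx[j, 2])^2 +
          (px[, 3] - lx[j, 3])^2
    near <- near | dz <= c2
  }
  if (!any(near)) {
    warning("no residue within ", cutoff, " A of the ligand; empty pocket")
    return(empty_pocket(cutoff, model))
  }
  hit_key <- unique(paste(prot$chain[near], prot$resno[near],
                          prot$insert[near]))
  in_pocket <- paste(prot$chain, prot$resno, prot$insert) %in% hit_key
  atoms <- prot[in_pocket, , drop = FALSE]
  rownames(atoms) <- NULL
  residues <- unique(atoms[, c("chain", "resno", "insert", "resname")])
  residues <- residues[order(residues$chain, residues$resno, residues$insert), ]
  rownames(residues) <- NULL
  base::structure(list(residues = residues, atoms = atoms, cutoff = cutoff,
                       model = model),
                  class = "pf_pocket")
}

empty_pocket <- function(cutoff, model) {
  base::structure(list(
    residues = data.frame(chain = character(), resno = integer(),
                          insert = character(), resname = character()),
    atoms = data.frame(), cutoff = cutoff, model = model),
    class = "pf_pocket")
}

#' @export
print.pf_pocket <- function(x, ...) {
  cat(sprintf("pf_pocket: %d residues / %d heavy atoms within %.1f A (model %d)\n",
              nrow(x$residues), nrow(x$atoms), x$cutoff, x$model))
  invisible(x)
}

#' Mean Kyte-Doolittle hydropathy of a pocket
#'
#' Unweighted mean of the per-residue hydropathy index over pocket residues.
#' Nonstandard residues are skipped with a warning.
#'
#' @param pocket A `pf_pocket`.
#' @return Mean hydropathy (dimensionless, in \[-4.5, 4.5\]).
#' @export
pocket_hydropathy <- function(pocket) {
  res <- pocket$residues
  if (nrow(res) == 0) stop("empty pocket: hydropathy undefined")
  kd <- kyte_doolittle()
  known <- res$resname %in% names(kd)
  if (any(!known)) {
    warning("skipping nonstandard residue(s): ",
            paste(unique(res$resname[!known]), collapse = ", "))
  }
  if (!any(known)) stop("no standard amino acids in pocket: hydropathy undefined")
  mean(kd[res$resname[known]])
}

#' Solvent-accessible surface area of a pocket
#'
#' Shrake-Rupley SASA summed over pocket-residue heavy atoms, evaluated in
#' the context of all heavy atoms of the model (protein and ligand), so
#' neighbouring atoms outside the pocket can bury pocket atoms.
#'
#' @param structure A `pf_structure`.
#' @param pocket A `pf_pocket` extracted from the same model.
#' @param probe Probe radius, Angstrom.
#' @param n_points Quadrature points per atom (>= 92).
#' @return Total pocket SASA in Angstrom^2.
#' @export
pocket_sasa <- function(structure, pocket, probe = 1.4, n_points = 960) {
  if (nrow(pocket$atoms) == 0) stop("empty pocket: SASA undefined")
  df <- model_atoms(structure, pocket$model, heavy_only = TRUE)
  akey <- paste(df$chain, df$resno, df$insert, df$name)
  pkey <- paste(pocket$atoms$chain, pocket$atoms$resno, pocket$atoms$insert,
                pocket$atoms$name)
  query <- which(akey %in% pkey)
  per_atom <- sasa_shrake_rupley(df[, c("x", "y", "z")], df$element,
                                 query = query, probe = probe,
                                 n_points = n_points)
  sum(per_atom)
}

#' Convex-hull volume and surface area of a pocket
#'
#' Volume (Angstrom^3) and surface area (Angstrom^2) of the convex hull of
#' the pocket's heavy-atom centers.
#'
#' @param pocket A `pf_pocket`.
#' @return list with `volume` and `area`.
#' @export
pocket_hull_metrics <- function(pocket) {
  if (nrow(pocket$atoms) < 4) {
    stop("pocket hull needs >= 4 heavy atoms, got ", nrow(pocket$atoms))
  }
  h <- convex_hull3(as.matrix(pocket$atoms[, c("x", "y", "z")]))
  list(volume = h$volume, area = h$area)
}

#' Magnitude of the pocket dipole moment
#'
#' Computes |sum_i q_i (r_i - rbar)| over pocket heavy atoms, where rbar is
#' the geometric center of the pocket heavy atoms. Because a pocket can
#' carry net charge, the origin is part of the definition and is returned
#' in the result. Two bundled charge schemes are selectable:
#' `"formal"` places unit charges on single side-chain atoms (Asp/Glu -1 on
#' the carboxylate carbon, Lys +1 on NZ, Arg +1 on CZ, His neutral, termini
#' ignored); `"partial_table"` uses a coarse bundled per-(residue, atom)
#' heavy-atom partial-charge table. Atoms without a table entry get charge 0.
#'
#' @param pocket A `pf_pocket`.
#' @param charge_scheme `"formal"` or `"partial_table"`.
#' @return list with `dipole_eA` (e*Angstrom), `dipole_D` (Debye),
#'   `vector` (e*Angstrom 3-vector), `origin`, `net_charge`, `scheme`.
#' @export
pocket_dipole <- function(pocket, charge_scheme = c("formal", "partial_table")) {
  charge_scheme <- match.arg(charge_scheme)
  at <- pocket$atoms
  if (is.null(at) || nrow(at) == 0) stop("empty pocket: dipole undefined")
  tab <- if (charge_scheme == "formal") formal_charge_table() else
    partial_charge_table()
  key <- paste(at$resname, at$name)
  q <- tab$charge[match(key, paste(tab$resname, tab$atom))]
  q[is.na(q)] <- 0
  xyz <- as.matrix(at[, c("x", "y", "z")])
  origin <- colMeans(xyz)
  mu <- colSums(q * sweep(xyz, 2, origin))
  list(dipole_eA = sqrt(sum(mu^2)),
       dipole_D = sqrt(sum(mu^2)) * EA_TO_DEBYE,
       vector = mu, origin = origin, net_charge = sum(q),
       scheme = charge_scheme)
}

#' Compute all five pocket descriptors for every model of a structure
#'
#' For each model: extract the pocket around the ligand and compute hull
#' volume and area, mean hydropathy, SASA, and dipole magnitude.
#'
#' @param structure A `pf_structure`.
#' @param ligand_selector Passed to [select_ligand()].
#' @param cutoff Pocket cutoff, Angstrom.
#' @param charge_scheme Charge scheme for the dipole (see [pocket_dipole()]).
#' @param probe,n_points SASA parameters (see [pocket_sasa()]).
#' @return data.frame with one row per model: `model`, `n_residues`,
#'   `volume_A3`, `area_A2`, `hydropathy`, `sasa_A2`, `dipole_eA`,
#'   `dipole_D`, `charge_scheme`, `origin_x/y/z`.
#' @export
compute_all_properties <- function(structure, ligand_selector, cutoff = 5.0,
                                   charge_scheme = "formal",
                                   probe = 1.4, n_points = 960) {
  nm <- n_models(structure)
  rows <- lapply(seq_len(nm), function(m) {
    lig <- select_ligand(structure, ligand_selector, model = m)
    pocket <- extract_pocket(structure, model = m, ligand = lig,
                             cutoff = cutoff)
    tryCatch({
      hull <- pocket_hull_metrics(pocket)
      dip <- pocket_dipole(pocket, charge_scheme)
      data.frame(
        model = m,
        n_residues = nrow(pocket$residues),
        volume_A3 = hull$volume,
        area_A2 = hull$area,
        hydropathy = pocket_hydropathy(pocket),
        sasa_A2 = pocket_sasa(structure, pocket, probe = probe,
                              n_points = n_points),
        dipole_eA = dip$dipole_eA,
        dipole_D = dip$dipole_D,
        charge_scheme = charge_scheme,
        origin_x = dip$origin[1], origin_y = dip$origin[2],
        origin_z = dip$origin[3],
        stringsAsFactors = FALSE)
    }, error = function(e) {
      stop("descriptor computation failed for model ", m, ": ",
           conditionMessage(e), call. = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
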