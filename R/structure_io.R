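#' Read a protein-ligand complex structure
#'
#' Parses a PDB or mmCIF file into a uniform atomic data model. Multi-model
#' files (e.g. the several models a structure predictor emits per protein)
#' yield one coordinate set per `MODEL` block sharing a single atom table.
#' Alternate locations are collapsed to a single conformer by keeping the
#' highest-occupancy altloc (ties broken by altloc letter order), so all
#' downstream pocket geometry is deterministic.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format One of `"auto"` (by file extension), `"pdb"`, `"mmcif"`.
#' @return An object of class `pf_structure`: a list with
#'   \describe{
#'     \item{atom}{data.frame with one row per atom: `name`, `element`,
#'       `resname`, `chain`, `resno`, `insert`, `is_hetero`, `occupancy`.}
#'     \item{coords}{list of `n_model` numeric matrices (atoms x 3), Angstrom.}
#'     \item{path}{source file.}
#'   }
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
      stop("cannot infer format from extension '.", ext,
           "'; pass format = 'pdb' or 'mmcif'"))
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      # read.cif emits advisory warnings (beta status, missing helix/sheet
      # blocks) that carry no information for atom parsing
      suppressWarnings(
        bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    stop("no atoms found in ", path)
  }
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- guess_element(at$elety[missing_el])
  }
  atom <- data.frame(
    name      = trimws(at$elety),
    element   = element,
    resname   = toupper(trimws(at$resid)),
    chain     = ifelse(is.na(at$chain), "A", at$chain),
    resno     = at$resno,
    insert    = ifelse(is.na(at$insert), "", at$insert),
    is_hetero = at$type == "HETATM",
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc    = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  nm <- max(1L, nrow(pdb$xyz))
  coords <- lapply(seq_len(nm), function(m) {
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  })
  st <- resolve_altlocs(atom, coords)
  st$path <- path
  validate_structure(st)
  st
}

# single-conformer reduction: keep the highest-occupancy altloc per atom
# site, ties by altloc letter order
resolve_altlocs <- function(atom, coords) {
  keep <- rep(TRUE, nrow(atom))
  has_alt <- atom$altloc != ""
  if (any(has_alt)) {
    key <- paste(atom$chain, atom$resno, atom$insert, atom$resname, atom$name)
    for (k in unique(key[has_alt])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        ord <- order(-atom$occupancy[idx], atom$altloc[idx])
        keep[idx[-ord[1]]] <- FALSE
      }
    }
  }
  atom <- atom[keep, , drop = FALSE]
  atom$altloc <- NULL
  rownames(atom) <- NULL
  coords <- lapply(coords, function(m) m[keep, , drop = FALSE])
  structure(list(atom = atom, coords = coords), class = "pf_structure")
}

validate_structure <- function(st) {
  if (nrow(st$atom) == 0) stop("structure contains zero atoms")
  if (any(st$atom$element == "")) stop("atoms with empty element symbol")
  ok <- vapply(st$coords, function(m) all(is.finite(m)), logical(1))
  if (!all(ok)) stop("non-finite coordinates in model(s) ",
                     paste(which(!ok), collapse = ", "))
  invisible(st)
}

#' Construct a structure object from an atom table and coordinates
#'
#' Low-level constructor used by the synthetic-structure generator and by
#' tests; performs the same validation as [read_structure()].
#'
#' @param atom data.frame with columns `name`, `element`, `resname`, `chain`,
#'   `resno`, `is_hetero`; optional `insert`, `occupancy`.
#' @param coords one atoms-x-3 matrix or a list of such matrices (one per model).
#' @return A `pf_structure` object.
#' @export
structure_from_atoms <- function(atom, coords) {
  if (is.matrix(coords)) coords <- list(coords)
  if (is.null(atom$insert)) atom$insert <- ""
  if (is.null(atom$occupancy)) atom$occupancy <- 1
  atom <- atom[, c("name", "element", "resname", "chain", "resno",
                   "insert", "is_hetero", "occupancy")]
  atom$element <- toupper(atom$element)
  stopifnot(all(vapply(coords, nrow, 0L) == nrow(atom)))
  st <- structure(list(atom = atom, coords = coords, path = NA_character_),
                  class = "pf_structure")
  validate_structure(st)
  st
}

guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA"), two,
         ifelse(one == "", "C", one))
}

#' @export
print.pf_structure <- function(x, ...) {
  cat(sprintf("pf_structure: %d atoms, %d model(s), %d hetero atoms\n",
              nrow(x$atom), n_models(x), sum(x$atom$is_hetero)))
  het <- unique(x$atom$resname[x$atom$is_hetero])
  if (length(het)) cat("  hetero residues:", paste(het, collapse = ", "), "\n")
  invisible(x)
}

#' Number of models in a structure
#' @param structure A `pf_structure`.
#' @return Integer model count.
#' @export
n_models <- function(structure) length(structure$coords)

#' Atom table with coordinates for one model
#'
#' @param structure A `pf_structure`.
#' @param model Model index (1-based).
#' @param heavy_only Drop hydrogens?
#' @return data.frame of atoms with `x`, `y`, `z` columns appended.
#' @export
model_atoms <- function(structure, model = 1, heavy_only = FALSE) {
  stopifnot(model >= 1, model <= n_models(structure))
  df <- structure$atom
  xyz <- structure$coords[[model]]
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  if (heavy_only) df <- df[df$element != "H", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select the ligand (dye) atoms of a structure
#'
#' @param structure A `pf_structure`.
#' @param selector Either a residue name (e.g. `"LIG"`) or a
#'   `list(chain =, resno =)` pair identifying one residue.
#' @param model Model index whose coordinates to attach.
#' @return data.frame of the matched residue's atoms (with coordinates).
#' @export
select_ligand <- function(structure, selector, model = 1) {
  df <- model_atoms(structure, model)
  if (is.character(selector) && length(selector) == 1) {
    hit <- df$resname == toupper(selector)
  } else if (is.list(selector)) {
    stopifnot(!is.null(selector$chain), !is.null(selector$resno))
    hit <- df$chain == selector$chain & df$resno == selector$resno
  } else {
    stop("selector must be a residue name or list(chain =, resno =)")
  }
  if (!any(hit)) {
    avail <- unique(df$resname[df$is_hetero])
    stop("ligand selector matched no residue; hetero residues present: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  out <- df[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-width ATOM/HETATM records; multi-model structures
#' get MODEL/ENDMDL blocks. Intended for normalized debugging output and
#' for the synthetic-structure generator.
#'
#' @param structure A `pf_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atom
  nm <- n_models(structure)
  con <- file(path, "w")
  on.exit(close(con))
  fmt_atom <- function(i, xyz, serial) {
    rec <- if (at$is_hetero[i]) "HETATM" else "ATOM  "
    name <- at$name[i]
    # atom-name column convention: 1-char elements start in column 14
    name <- if (nchar(name) < 4 && nchar(at$element[i]) == 1) {
      sprintf(" %-3s", name)
    } else sprintf("%-4s", name)
    sprintf("%s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, at$resname[i], at$chain[i], at$resno[i],
            ifelse(at$insert[i] == "", " ", at$insert[i]),
            xyz[i, 1], xyz[i, 2], xyz[i, 3], at$occupancy[i], 0,
            at$element[i])
  }
  for (m in seq_len(nm)) {
    if (nm > 1) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- structure$coords[[m]]
    writeLines(vapply(seq_len(nrow(at)),
                      function(i) fmt_atom(i, xyz, i), ""), con)
    if (nm > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
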