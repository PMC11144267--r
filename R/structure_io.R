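#' @section Structure model:
#' A structure is an ordinary tibble of atoms (class `pore_structure`) with
#' one row per atom and columns `atom` (index), `atom_name`, `element`,
#' `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`, `occupancy`,
#' `b_factor`, `is_protein`, `is_water`, `is_ion`, `subunit` (1-based index
#' over protein chains, `NA` for solvent), `vdw_radius` and `hydro_const`.
#' All tidyverse verbs apply; the class only carries printing and method
#' dispatch.
#' @name poremapr
NULL

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
         "MSE","HSD","HSE","HSP","HID","HIE","HIP")
WATER3 <- c("HOH","WAT","TIP","TIP3","SOL","H2O")
ION3 <- c("NA","CL","K","MG","ZN","CA","CAL","SOD","CLA","POT")

new_structure <- function(df) {
  df <- as_tibble(df)
  class(df) <- c("pore_structure", class(df))
  df
}

#' Build a structure from an atom table
#'
#' Validates the atom table, derives protein/water/ion flags from residue
#' names, numbers the protein chains as subunits (order of first appearance)
#' and assigns van der Waals radii from the shipped element table.
#'
#' @param df Data frame with at least `atom_name`, `element`, `residue_name`,
#'   `residue_number`, `chain_id`, `x`, `y`, `z`.
#' @return A `pore_structure` tibble.
#' @export
as_structure <- function(df) {
  need <- c("atom_name", "element", "residue_name", "residue_number",
            "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste("atom table lacks columns:",
                                paste(miss, collapse = ", ")))
  df <- as_tibble(df)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    abort("non-finite atom coordinates")
  if (!"occupancy" %in% names(df)) df$occupancy <- 1
  if (!"b_factor" %in% names(df)) df$b_factor <- 0
  rn <- toupper(df$residue_name)
  df$is_water <- rn %in% WATER3
  # single-atom CA/K/NA... residues are ions even though CA is also calcium's
  # element symbol; protein CA atoms sit inside amino-acid residues
  df$is_ion <- rn %in% ION3 & !(rn %in% AA3)
  df$is_protein <- rn %in% AA3
  df$atom <- seq_len(nrow(df))
  pchain <- unique(df$chain_id[df$is_protein])
  df$subunit <- ifelse(df$is_protein, match(df$chain_id, pchain), NA_integer_)
  key <- paste(df$chain_id, df$residue_number, df$residue_name, df$atom_name)
  if (anyDuplicated(key[df$is_protein]))
    abort("duplicate atom identifiers after altloc resolution")
  df <- assign_radii(df)
  if (!"hydro_const" %in% names(df)) df$hydro_const <- NA_real_
  cols <- c("atom", "atom_name", "element", "residue_name", "residue_number",
            "chain_id", "x", "y", "z", "occupancy", "b_factor",
            "is_protein", "is_water", "is_ion", "subunit",
            "vdw_radius", "hydro_const")
  new_structure(df[, c(cols, setdiff(names(df), cols))])
}

assign_radii <- function(df, table = vdw_radius_table()) {
  r <- setNames(table$vdw_radius, toupper(table$element))
  el <- toupper(df$element)
  v <- unname(r[el])
  v[is.na(v)] <- r[["DEFAULT"]]
  df$vdw_radius <- v
  df
}

element_from_name <- function(atom_name, residue_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  el <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "SE")]
  # monatomic ion residues keep their full symbol
  ion <- toupper(residue_name) %in% ION3 & !(toupper(residue_name) %in% AA3)
  el[ion] <- toupper(residue_name[ion])
  el[el == "SOD"] <- "NA"; el[el == "CLA"] <- "CL"
  el[el == "POT"] <- "K"; el[el == "CAL"] <- "CA"
  el
}

#' Read a protein structure from PDB or mmCIF
#'
#' Author residue numbering is preserved. Alternate locations are resolved to
#' the highest-occupancy conformer (first seen on ties); waters and ions are
#' kept in the atom table but flagged so protein-only operations can exclude
#' them.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `pore_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("file not found:", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste("unreadable structure file:",
                                    conditionMessage(e))))
  at <- pdb$atom
  if (nrow(at) == 0) abort("structure file contains no atoms")
  at$chain[is.na(at$chain)] <- "A"
  # altloc: keep the highest-occupancy conformer per atom, first seen on ties
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    ord <- order(key, -at$o, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$resid, at$elety)), ,
             drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  bad <- is.na(el) | !nzchar(trimws(el))
  el[bad] <- element_from_name(at$elety[bad], at$resid[bad])
  df <- tibble(atom_name = trimws(at$elety), element = toupper(trimws(el)),
               residue_name = trimws(at$resid), residue_number = at$resno,
               chain_id = at$chain, x = at$x, y = at$y, z = at$z,
               occupancy = ifelse(is.na(at$o), 1, at$o),
               b_factor = ifelse(is.na(at$b), 0, at$b))
  s <- as_structure(df)
  if (!any(s$is_protein)) abort("structure contains no protein atoms")
  s
}

#' Write a structure to PDB
#'
#' @param s A `pore_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  bio3d::write.pdb(file = path,
                   eleno = s$atom, elety = s$atom_name, resid = s$residue_name,
                   chain = s$chain_id, resno = s$residue_number,
                   xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
                   o = s$occupancy, b = s$b_factor, elesy = s$element)
  invisible(path)
}

#' Write the normalised atom table as TSV (debug aid)
#' @inheritParams write_structure
#' @export
write_atom_table <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign atomic hydrophobicity constants
#'
#' Types every protein heavy atom with its united-atom Wildman-Crippen logP
#' contribution (hydrogens, when present in the file, get constant 0 since
#' their contributions are already folded into the heavy atoms). Non-protein
#' atoms are left `NA`; they never enter MHP sums.
#'
#' @param s A `pore_structure`.
#' @param scheme Typing table, by default [hydrophobicity_table()].
#' @param on_missing What to do for an untypeable protein heavy atom:
#'   `"error"` (default, reports residue identity), `"zero"` or `"na"`.
#' @return `s` with `hydro_const` filled.
#' @export
assign_hydrophobicity <- function(s, scheme = hydrophobicity_table(),
                                  on_missing = c("error", "zero", "na")) {
  on_missing <- match.arg(on_missing)
  key <- paste(toupper(s$residue_name), toupper(s$atom_name))
  lut <- setNames(scheme$f, paste(toupper(scheme$residue),
                                  toupper(scheme$atom)))
  # terminal/variant fallbacks: OXT behaves like the backbone carbonyl O
  lut[paste(unique(toupper(scheme$residue)), "OXT")] <-
    lut[paste(unique(toupper(scheme$residue)), "O")]
  f <- unname(lut[key])
  f[s$element == "H"] <- 0
  target <- s$is_protein & s$element != "H"
  bad <- target & is.na(f)
  if (any(bad)) {
    who <- unique(paste0(s$residue_name[bad], s$residue_number[bad], ":",
                         s$atom_name[bad]))
    msg <- paste("untypeable atoms:", paste(head(who, 8), collapse = ", "))
    if (on_missing == "error") abort(msg)
    if (on_missing == "zero") f[bad] <- 0
    warn(msg)
  }
  s$hydro_const <- ifelse(target | s$element == "H", f, NA_real_)
  s
}

# protein-atom coordinate matrix + typed fields, shared by the field kernels
protein_xyz <- function(s) {
  p <- s[s$is_protein, , drop = FALSE]
  list(xyz = as.matrix(p[, c("x", "y", "z")]), f = p$hydro_const,
       subunit = p$subunit, radius = p$vdw_radius, atom = p$atom,
       n_subunits = max(p$subunit))
}

#' Select atoms of given residues
#'
#' @param s A `pore_structure`.
#' @param residues Integer residue numbers (author numbering).
#' @param chain Optional chain filter.
#' @param atom_names Optional atom-name filter (e.g. `"CA"`).
#' @return A `pore_structure` subset.
#' @export
residue_atoms <- function(s, residues, chain = NULL, atom_names = NULL) {
  out <- s[s$residue_number %in% residues & s$is_protein, , drop = FALSE]
  if (!is.null(chain)) out <- out[out$chain_id %in% chain, , drop = FALSE]
  if (!is.null(atom_names))
    out <- out[out$atom_name %in% atom_names, , drop = FALSE]
  out
}

# --------------------------------------------------------------------------
# Frame series: a topology plus a [n_atom x 3 x n_frame] coordinate array

#' Construct a frame series
#'
#' @param topology A `pore_structure` describing every atom.
#' @param coords Numeric array `n_atom x 3 x n_frame`.
#' @param times Frame time stamps (same length as the third dimension).
#' @return A `frame_series` object.
#' @export
frame_series <- function(topology, coords, times = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    abort("coords must be an n_atom x 3 x n_frame array")
  if (dim(coords)[1] != nrow(topology))
    abort("frame atom count does not match topology")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf)
  if (length(times) != nf) abort("times length must equal frame count")
  structure(list(topology = topology, coords = coords, times = times),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("<frame_series> ", dim(x$coords)[3], " frames x ", nrow(x$topology),
      " atoms, t = [", min(x$times), ", ", max(x$times), "]\n", sep = "")
  invisible(x)
}

n_frames <- function(series) dim(series$coords)[3]

# coordinates of frame k substituted into the topology table
frame_structure <- function(series, k) {
  s <- series$topology
  s$x <- series$coords[, 1, k]
  s$y <- series$coords[, 2, k]
  s$z <- series$coords[, 3, k]
  s
}

#' Last-fraction analysis window
#'
#' Convenience selector for [load_frames()]/[window_frames()]: e.g.
#' `last_frac(0.25)` keeps the final quarter of the trajectory (the package
#' convention for "analyse the tail of the run, once the pore has
#' equilibrated").
#' @param frac Fraction of the total time span to keep, from the end.
#' @export
last_frac <- function(frac) {
  stopifnot(frac > 0, frac <= 1)
  structure(list(frac = frac), class = "pm_last_frac")
}

resolve_window <- function(times, window) {
  if (is.null(window)) return(c(min(times), max(times)))
  if (inherits(window, "pm_last_frac")) {
    t1 <- max(times)
    t0 <- t1 - window$frac * (t1 - min(times))
    # strictly-after boundary so last_frac(0.25) of 200 frames keeps 50
    return(c(t0 + 1e-9, t1))
  }
  if (!is.numeric(window) || length(window) != 2)
    abort("window must be NULL, c(t0, t1), or last_frac(f)")
  sort(window)
}

#' Restrict a frame series to an analysis window
#' @param series A `frame_series`.
#' @param window `NULL` (all frames), a numeric time interval `c(t0, t1)`, or
#'   [last_frac()].
#' @export
window_frames <- function(series, window = NULL) {
  w <- resolve_window(series$times, window)
  keep <- series$times >= w[1] & series$times <= w[2]
  if (!any(keep)) abort("analysis window contains no frames")
  frame_series(series$topology,
               series$coords[, , keep, drop = FALSE],
               series$times[keep])
}

#' Load trajectory frames (multi-model PDB)
#'
#' Reads coordinate frames for an existing topology from a multi-model PDB
#' file, checks the atom count against the topology and restricts to the
#' analysis window. Frame order is preserved.
#'
#' @param topology A `pore_structure`.
#' @param trajectory Path to a multi-model PDB file.
#' @param window See [window_frames()].
#' @param dt Time per frame used to stamp frames (arbitrary units).
#' @return A `frame_series`.
#' @export
load_frames <- function(topology, trajectory, window = NULL, dt = 1) {
  pdb <- tryCatch(bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    abort(paste("unreadable trajectory:",
                                conditionMessage(e))))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  na <- ncol(xyz) / 3
  if (na != nrow(topology))
    abort(sprintf("trajectory atom count (%d) does not match topology (%d)",
                  na, nrow(topology)))
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(na, 3, nf))
  for (k in seq_len(nf))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  series <- frame_series(topology, coords, times = dt * seq_len(nf))
  window_frames(series, window)
}

#' Write a frame series as multi-model PDB
#' @param series A `frame_series`.
#' @param path Output file.
#' @export
write_frames <- function(series, path) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (k in seq_len(n_frames(series))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    write_structure(frame_structure(series, k), tmp)
    lines <- readLines(tmp)
    writeLines(lines[grepl("^(ATOM|HETATM|TER)", lines)], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
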