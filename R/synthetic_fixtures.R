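# --- internal peptide construction (NeRF chain extension) ------------------

# place atom D given positions A, B, C, bond |C-D|, angle B-C-D (deg),
# torsion A-B-C-D (deg)
nerf_place <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + cbind(bc, m, n) %*% d2
}

# ordered side-chain atom names per residue, from the shipped typing table
sidechain_atoms <- function(resname) {
  tab <- hydrophobicity_table()
  nm <- tab$atom[tab$residue == resname]
  el <- tab$element[tab$residue == resname]
  keep <- !(nm %in% BACKBONE_ATOMS)
  list(names = nm[keep], elements = el[keep])
}

#' Build an idealised peptide chain
#'
#' Backbone (N, CA, C, O) generated by natural-extension chain building
#' with standard bond geometry and the given backbone torsions; side chains
#' are simplified extended stubs: the real heavy-atom composition of each
#' residue (correct atom names, hence correct hydrophobicity typing)
#' placed along the outward C-alpha to C-beta direction at 1.35 Angstrom
#' spacing. Good enough geometry for surface, field and hydrogen-bond
#' operators; not a rotamer model.
#'
#' @param sequence Character vector of 3-letter residue codes.
#' @param phi,psi Backbone torsions in degrees, scalars or per-residue
#'   vectors (alpha helix -57/-47; pi helix -80/-55; extended -120/120).
#' @param chain_id Chain label.
#' @return A `pore_structure`.
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, chain_id = "A") {
  n <- length(sequence)
  sequence <- toupper(sequence)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7; a_CaCO <- 120.8
  rows <- list()
  # seed frame for the first residue
  Npos <- c(0, 0, 0)
  CApos <- c(b_NCa, 0, 0)
  Cpos <- CApos + c(b_CaC * cos(pi * (180 - a_NCaC) / 180),
                    b_CaC * sin(pi * (180 - a_NCaC) / 180), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Npos <- nerf_place(prevN, prevCA, prevC, b_CN, a_CaCN, psi[i - 1])
      CApos <- nerf_place(prevCA, prevC, Npos, b_NCa, a_CNCa, 180)  # omega
      Cpos <- nerf_place(prevC, Npos, CApos, b_CaC, a_NCaC, phi[i])
    }
    Opos <- nerf_place(Npos, CApos, Cpos, b_CO, a_CaCO, psi[i] + 180)
    res <- sequence[i]
    add <- function(nm, el, p) rows[[length(rows) + 1]] <<-
      tibble(atom_name = nm, element = el, residue_name = res,
             residue_number = i, chain_id = chain_id,
             x = p[1], y = p[2], z = p[3])
    add("N", "N", Npos); add("CA", "C", CApos)
    add("C", "C", Cpos); add("O", "O", Opos)
    sc <- sidechain_atoms(res)
    if (length(sc$names)) {
      CB <- nerf_place(Cpos, Npos, CApos, 1.53, 110.4, -122.6)
      u <- CB - CApos; u <- u / sqrt(sum(u^2))
      for (k in seq_along(sc$names)) {
        p <- CApos + (1.53 + 1.35 * (k - 1)) * u
        add(sc$names[k], sc$elements[k], p)
      }
    }
    prevN <- Npos; prevCA <- CApos; prevC <- Cpos
  }
  as_structure(bind_rows(rows))
}

#' Specification of a synthetic C4-symmetric pore
#'
#' @param n_res Residues per helix (default 22).
#' @param lumen_radius Target minimal pore radius (Angstrom).
#' @param sequence Residue codes per helix position; default is a
#'   leucine/alanine helix with an Ile "gate" ring and an Asn ring one turn
#'   above it (positions `gate_pos` and `gate_pos - 4`), mimicking the
#'   I679/N676-style architecture of TRPV pores.
#' @param gate_pos Helix position of the gate ring.
#' @param tilt Helix tilt off the pore axis, degrees.
#' @param pi_window Optional residue interval built with pi-helical
#'   torsions (engineered pi-bulge); `NULL` for a pure alpha helix.
#' @param seed Integer seed stored with the spec.
#' @export
pore_spec <- function(n_res = 22, lumen_radius = 2.3, sequence = NULL,
                      gate_pos = 15, tilt = 0, pi_window = NULL, seed = 1) {
  if (is.null(sequence)) {
    sequence <- rep(c("LEU", "ALA"), length.out = n_res)
    sequence[gate_pos] <- "ILE"
    if (gate_pos > 4) sequence[gate_pos - 4] <- "ASN"
  }
  stopifnot(length(sequence) == n_res)
  list(n_helices = 4, n_res = n_res, lumen_radius = lumen_radius,
       sequence = toupper(sequence), gate_pos = gate_pos, tilt = tilt,
       pi_window = pi_window, seed = seed)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

apply_rot <- function(s, R) {
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

# minimal clearance between the z-axis and the VdW surface (C4 pores are
# centred, so this is the on-axis gate radius)
axis_clearance <- function(s) {
  p <- s[s$is_protein, , drop = FALSE]
  min(sqrt(p$x^2 + p$y^2) - p$vdw_radius)
}

#' Generate a C4-symmetric four-helix toy pore
#'
#' Builds one idealised helix, orients it along z with the chosen gate-ring
#' face pointing to the pore axis, tilts and places it on a circle, then
#' replicates it by exact 90-degree rotations (chains A-D). The circle
#' radius is calibrated so the minimal on-axis lumen radius matches
#' `spec$lumen_radius` (fixed-point iteration on the clearance).
#'
#' @param spec A [pore_spec()].
#' @return A typed `pore_structure` (hydrophobicity constants assigned).
#' @export
make_c4_pore <- function(spec = pore_spec()) {
  phi <- rep(-57, spec$n_res); psi <- rep(-47, spec$n_res)
  if (!is.null(spec$pi_window)) {
    w <- seq(spec$pi_window[1], spec$pi_window[2])
    phi[w] <- -80; psi[w] <- -55
  }
  h <- build_peptide(spec$sequence, phi = phi, psi = psi, chain_id = "A")
  ax <- helix_axis(h)
  h <- rotate_structure(h, rotation_to_z(ax$direction), ax$center)
  # rotate about own axis so the gate residue's side chain faces -x
  cb <- h[h$residue_number == spec$gate_pos &
            h$atom_name %in% c("CB", "CA"), , drop = FALSE]
  dirv <- if (any(cb$atom_name == "CB"))
    c(cb$x[cb$atom_name == "CB"] - cb$x[cb$atom_name == "CA"],
      cb$y[cb$atom_name == "CB"] - cb$y[cb$atom_name == "CA"])
  else c(cb$x[1], cb$y[1])
  h <- apply_rot(h, rot_z(180 - atan2(dirv[2], dirv[1]) * 180 / pi))
  if (spec$tilt != 0) {
    a <- spec$tilt * pi / 180
    Rt <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
                 byrow = TRUE)
    h <- apply_rot(h, Rt)
  }
  vmax <- max(h$vdw_radius)
  if (spec$lumen_radius <= vmax)
    abort("infeasible geometry: lumen radius must exceed the largest VdW radius")
  D <- spec$lumen_radius + 6   # initial circle radius guess
  assemble <- function(D) {
    h1 <- h; h1$x <- h1$x + D
    parts <- purrr::map(0:3, function(k) {
      hk <- apply_rot(h1, rot_z(90 * k))
      hk$chain_id <- LETTERS[k + 1]
      hk
    })
    as_structure(bind_rows(parts))
  }
  s <- assemble(D)
  for (it in 1:4) {
    err <- spec$lumen_radius - axis_clearance(s)
    if (abs(err) < 0.02) break
    D <- D + err
    s <- assemble(D)
  }
  assign_hydrophobicity(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate hydrated pseudo-trajectory frames for a pore
#'
#' Waters (single-oxygen particles) are drawn uniformly in the lumen
#' cylinder each frame, optionally excluding a dry z band (a dewetted
#' gate); ions sit on the axis, or walk monotonically through the gate when
#' `walk_ion` is set; protein coordinates receive per-frame seeded Gaussian
#' jitter. Frames are statistical stand-ins, not dynamics, and are
#' bit-reproducible for a fixed seed.
#'
#' @param s A typed `pore_structure` (e.g. from [make_c4_pore()]).
#' @param n_frames Number of frames.
#' @param water_density Waters per cubic Angstrom of lumen cylinder
#'   (default 0.033, the bulk-water number density).
#' @param ion_count Ions placed on the axis (default 0).
#' @param jitter Gaussian positional noise for protein atoms (Angstrom).
#' @param cyl_radius Lumen cylinder radius for water placement; default:
#'   on-axis clearance + 1.5.
#' @param z_range Axial extent for water placement; default: protein z
#'   range shrunk by 2 Angstrom.
#' @param dry_band Optional z interval kept water-free.
#' @param walk_ion If `TRUE`, one extra ion traverses `z_range` bottom to
#'   top across the frames.
#' @param seed RNG seed (deterministic output).
#' @return A `frame_series` whose topology includes the waters and ions.
#' @export
make_hydrated_frames <- function(s, n_frames = 5, water_density = 0.033,
                                 ion_count = 0, jitter = 0.05,
                                 cyl_radius = NULL, z_range = NULL,
                                 dry_band = NULL, walk_ion = FALSE,
                                 seed = 1) {
  stopifnot(jitter >= 0, n_frames >= 1)
  cyl_radius <- cyl_radius %||% (axis_clearance(s) + 1.5)
  if (cyl_radius <= 0) abort("infeasible water cylinder radius")
  zr <- z_range %||% (range(s$z[s$is_protein]) + c(2, -2))
  nw <- max(1, round(water_density * pi * cyl_radius^2 * diff(zr)))
  draw_waters <- function() {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < nw) {
      m <- nw - nrow(out)
      r <- cyl_radius * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      z <- stats::runif(m, zr[1], zr[2])
      ok <- if (is.null(dry_band)) rep(TRUE, m)
            else !(z >= dry_band[1] & z <= dry_band[2])
      out <- rbind(out, cbind(r * cos(th), r * sin(th), z)[ok, , drop = FALSE])
    }
    out[seq_len(nw), , drop = FALSE]
  }
  n_ion <- ion_count + as.integer(walk_ion)
  wat <- tibble(atom_name = "O", element = "O", residue_name = "HOH",
                residue_number = seq_len(nw), chain_id = "W",
                x = 0, y = 0, z = 0)
  ion <- if (n_ion > 0)
    tibble(atom_name = "NA", element = "NA", residue_name = "NA",
           residue_number = seq_len(n_ion), chain_id = "I",
           x = 0, y = 0, z = 0) else NULL
  prot_cols <- c("atom_name", "element", "residue_name", "residue_number",
                 "chain_id", "x", "y", "z")
  top <- as_structure(bind_rows(s[, prot_cols], wat, ion))
  top <- assign_hydrophobicity(top, on_missing = "na")
  np <- nrow(s)
  coords <- array(NA_real_, c(nrow(top), 3, n_frames))
  with_seed(seed, {
    ion_z0 <- if (ion_count > 0) seq(zr[1], zr[2],
                                     length.out = ion_count + 2)[-c(1, ion_count + 2)]
              else numeric()
    for (k in seq_len(n_frames)) {
      pxyz <- as.matrix(s[, c("x", "y", "z")]) +
        matrix(stats::rnorm(3 * np, 0, jitter), np, 3)
      wxyz <- draw_waters()
      ixyz <- NULL
      if (n_ion > 0) {
        zi <- ion_z0
        if (walk_ion) {
          zw <- zr[1] + (k - 1) / max(1, n_frames - 1) * diff(zr)
          zi <- c(zi, zw)
        }
        ixyz <- cbind(0, 0, zi)
      }
      coords[, , k] <- rbind(pxyz, wxyz, ixyz)
    }
  })
  frame_series(top, coords, times = seq_len(n_frames))
}
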