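#' Build the pore axis from symmetry-related C-alpha quadruplets
#'
#' For each listed residue the centre of mass of its C-alpha atoms across the
#' four subunits gives one control point; a cubic spline through the control
#' points (ordered and parameterised by z) gives the axis curve. For a
#' C4-symmetric assembly the curve coincides with the symmetry axis.
#'
#' @param s A `pore_structure` (tetramer).
#' @param axis_residues Residue numbers defining the axis, e.g.
#'   `channel_config("trpv1")$axis_residues`.
#' @return A `pore_axis` object: tibble of control points plus spline
#'   interpolants `fx(z)`, `fy(z)` as attributes.
#' @export
build_pore_axis <- function(s, axis_residues) {
  ca <- residue_atoms(s, axis_residues, atom_names = "CA")
  nsub <- max(s$subunit, na.rm = TRUE)
  pts <- ca |>
    group_by(.data$residue_number) |>
    summarise(n_sub = dplyr::n_distinct(.data$subunit),
              x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
  missing <- setdiff(axis_residues, pts$residue_number)
  if (length(missing))
    abort(paste("axis residues absent from structure:",
                paste(missing, collapse = ", ")))
  if (any(pts$n_sub < nsub))
    abort(paste("axis residues missing in some subunits:",
                paste(pts$residue_number[pts$n_sub < nsub], collapse = ", ")))
  if (nrow(pts) < 2) abort("need at least 2 axis control points")
  pts <- arrange(pts, .data$z)
  if (anyDuplicated(pts$z)) pts$z <- pts$z + cumsum(duplicated(pts$z)) * 1e-9
  method <- if (nrow(pts) >= 3) "natural" else "monoH.FC"
  fx <- splinefun(pts$z, pts$x, method = method)
  fy <- splinefun(pts$z, pts$y, method = method)
  structure(select(pts, -"n_sub"),
            fx = fx, fy = fy, z_range = range(pts$z),
            class = c("pore_axis", class(pts)))
}

#' Evaluate axis points and local tangent frames
#'
#' @param axis A `pore_axis`.
#' @param z Axial coordinates (may extend slightly beyond the control span;
#'   the spline extrapolates linearly there).
#' @return Tibble with axis point, unit tangent, and two in-plane unit
#'   vectors `e1`, `e2` spanning the plane orthogonal to the tangent.
#' @export
axis_frame <- function(axis, z) {
  fx <- attr(axis, "fx"); fy <- attr(axis, "fy")
  px <- fx(z); py <- fy(z)
  tx <- fx(z, deriv = 1); ty <- fy(z, deriv = 1)
  tn <- cbind(tx, ty, 1)
  tn <- tn / sqrt(rowSums(tn^2))
  # e1: global x projected off the tangent (axes here are near-straight and
  # near-vertical, so this frame is smooth in z)
  e1 <- cbind(1 - tn[, 1]^2, -tn[, 1] * tn[, 2], -tn[, 1] * tn[, 3])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(tn[, 2] * e1[, 3] - tn[, 3] * e1[, 2],
              tn[, 3] * e1[, 1] - tn[, 1] * e1[, 3],
              tn[, 1] * e1[, 2] - tn[, 2] * e1[, 1])
  tibble(z = z, px = px, py = py, pz = z,
         tx = tn[, 1], ty = tn[, 2], tz = tn[, 3],
         e1x = e1[, 1], e1y = e1[, 2], e1z = e1[, 3],
         e2x = e2[, 1], e2y = e2[, 2], e2z = e2[, 3])
}

# largest clear-sphere radius centred in the plane orthogonal to the axis at
# one z: Nelder-Mead over in-plane displacement (u, v), seeded on the axis,
# displacement-limited so the probe cannot escape the pore sideways
plane_radius <- function(frame_row, axyz, radii, max_disp, max_radius) {
  p0 <- c(frame_row$px, frame_row$py, frame_row$pz)
  e1 <- c(frame_row$e1x, frame_row$e1y, frame_row$e1z)
  e2 <- c(frame_row$e2x, frame_row$e2y, frame_row$e2z)
  clear <- function(uv) {
    c0 <- p0 + uv[1] * e1 + uv[2] * e2
    d <- sqrt((axyz[, 1] - c0[1])^2 + (axyz[, 2] - c0[2])^2 +
              (axyz[, 3] - c0[3])^2) - radii
    min(d)
  }
  obj <- function(uv) {
    pen <- max(0, sqrt(sum(uv^2)) - max_disp)
    -clear(uv) + 1e3 * pen^2
  }
  # coarse seed scan (within the displacement limit) keeps Nelder-Mead out
  # of shallow local maxima
  g <- seq(-max_disp, max_disp, length.out = 5)
  seeds <- rbind(c(0, 0), as.matrix(expand.grid(u = g, v = g)))
  seeds <- seeds[sqrt(rowSums(seeds^2)) <= max_disp + 1e-9, , drop = FALSE]
  vals <- apply(seeds, 1, clear)
  best <- seeds[which.max(vals), ]
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 400))
  r <- max(clear(opt$par), max(vals))   # never worse than the best seed
  list(radius = min(r, max_radius), capped = r > max_radius,
       converged = opt$convergence == 0)
}

#' Pore-radius profile (HOLE-style)
#'
#' At each position along the axis the pore radius is the radius of the
#' largest sphere, centred anywhere in the plane orthogonal to the local
#' axis tangent, that touches no van der Waals sphere. The centre search is
#' a displacement-limited Nelder-Mead seeded on the axis point (plus a
#' coarse in-plane scan), reproducing the semantics of the classic HOLE
#' profiling tool.
#'
#' @param s A `pore_structure`; protein atoms with VdW radii are used.
#' @param axis A `pore_axis` from [build_pore_axis()].
#' @param z_step Grid spacing in Angstrom (default 0.25).
#' @param z_range Optional z interval; defaults to the axis control span.
#' @param max_radius Cap for locally unbounded sections (flagged).
#' @param max_disp Maximum in-plane centre displacement off the axis.
#' @param atom_range Atoms farther than this from the axis point are ignored
#'   at each z (search locality).
#' @return A `radius_profile` tibble: `z`, `radius`, `capped`, `converged`.
#' @export
radius_profile <- function(s, axis, z_step = 0.25, z_range = NULL,
                           max_radius = 15, max_disp = 5, atom_range = 25) {
  pr <- protein_xyz(s)
  if (nrow(pr$xyz) == 0) abort("no protein atoms")
  zr <- z_range %||% attr(axis, "z_range")
  zg <- seq(zr[1], zr[2], by = z_step)
  fr <- axis_frame(axis, zg)
  res <- purrr::map(seq_len(nrow(fr)), function(i) {
    p0 <- c(fr$px[i], fr$py[i], fr$pz[i])
    d2 <- (pr$xyz[, 1] - p0[1])^2 + (pr$xyz[, 2] - p0[2])^2 +
          (pr$xyz[, 3] - p0[3])^2
    keep <- d2 < atom_range^2
    if (!any(keep))
      return(list(radius = max_radius, capped = TRUE, converged = TRUE))
    plane_radius(fr[i, ], pr$xyz[keep, , drop = FALSE], pr$radius[keep],
                 max_disp, max_radius)
  })
  out <- tibble(z = zg,
                radius = purrr::map_dbl(res, "radius"),
                capped = purrr::map_lgl(res, "capped"),
                converged = purrr::map_lgl(res, "converged"))
  out$radius <- pmax(out$radius, 0)
  class(out) <- c("radius_profile", class(out))
  out
}

#' Minimal pore radius within a gate region
#'
#' @param profile A `radius_profile`.
#' @param gate_region Numeric z interval `c(z0, z1)`.
#' @return The minimum radius over the region (ties resolved to the smallest
#'   z; the position is attached as attribute `z_min`).
#' @export
gate_radius <- function(profile, gate_region) {
  stopifnot(length(gate_region) == 2)
  gate_region <- sort(gate_region)
  sel <- profile$z >= gate_region[1] & profile$z <= gate_region[2]
  if (!any(sel)) abort("gate region contains no profile points")
  r <- profile$radius[sel]
  z <- profile$z[sel]
  i <- which.min(r)  # which.min takes the first (smallest z) on ties
  structure(r[i], z_min = z[i])
}

#' Gate z-window from configured gate residues
#'
#' Resolves a channel's gate residue list to an axial window: the z span of
#' their C-alpha atoms across subunits, padded by `margin`.
#' @param s A `pore_structure`.
#' @param gate_residues Residue numbers forming the activation gate.
#' @param margin Padding in Angstrom (default 3).
#' @export
gate_region_z <- function(s, gate_residues, margin = 3) {
  ca <- residue_atoms(s, gate_residues, atom_names = "CA")
  if (nrow(ca) == 0) abort("gate residues not found")
  range(ca$z) + c(-margin, margin)
}
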