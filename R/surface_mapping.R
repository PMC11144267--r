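#' Ray-trace a cylindrical projection map of the van der Waals surface
#'
#' Implements the five-step projection: (1) the pore axis; (2) a regular
#' (z, angle) grid on an enclosing projection cylinder, one ray per node
#' starting on the local axis point and running orthogonal to the local
#' tangent; (3) each ray traced to its nearest intersection with a van der
#' Waals sphere, accelerated by 3DDDA voxel traversal with early exit;
#' (4) the property evaluated at the hit point; (5) values collected on the
#' 2D grid. Tangent rays count as hits (closed spheres). Rows whose rays all
#' miss are flagged.
#'
#' @param s A typed `pore_structure`.
#' @param axis A `pore_axis` (see [build_pore_axis()]) or the result of
#'   [helix_axis()] turned into a straight axis internally.
#' @param z_step,angle_step Grid spacing (Angstrom, degrees).
#' @param z_range Axial span; defaults to the axis control span.
#' @param property `"mhp"` (self/induced/total per node, owner = subunit of
#'   the hit atom) or `"residue_score"` (per-residue values looked up from
#'   `scores`).
#' @param scores For `property = "residue_score"`: tibble with `chain_id`,
#'   `residue_number`, `score`.
#' @param trace_atoms Optional `atom` indices to trace against (default: all
#'   protein atoms). MHP is always evaluated against the full protein.
#' @param params [mhp_params()].
#' @param voxel_size Voxel edge for the traversal grid (Angstrom).
#' @return A `cyl_map` tibble: `z`, `angle`, `hit`, `hit_atom`,
#'   `hit_subunit`, hit-point coordinates `hx, hy, hz`, and the property
#'   columns (`self`, `induced`, `total` for MHP; `score` otherwise).
#'   Attribute `projection_radius` encloses all traced atoms in every
#'   section.
#' @export
trace_map <- function(s, axis, z_step = 0.5, angle_step = 2,
                      z_range = NULL, property = c("mhp", "residue_score"),
                      scores = NULL, trace_atoms = NULL,
                      params = mhp_params(), voxel_size = 3) {
  property <- match.arg(property)
  pr <- s[s$is_protein, , drop = FALSE]
  if (!is.null(trace_atoms)) pr <- pr[pr$atom %in% trace_atoms, , drop = FALSE]
  if (nrow(pr) == 0) abort("no atoms to trace against")
  zr <- z_range %||% attr(axis, "z_range")
  zg <- seq(zr[1], zr[2], by = z_step)
  ag <- seq(0, 360 - angle_step, by = angle_step)
  fr <- axis_frame(axis, zg)
  # projection radius: encloses every traced sphere in every section
  dx <- pr$x - attr(axis, "fx")(pmin(pmax(pr$z, zr[1]), zr[2]))
  dy <- pr$y - attr(axis, "fy")(pmin(pmax(pr$z, zr[1]), zr[2]))
  rproj <- max(sqrt(dx^2 + dy^2) + pr$vdw_radius) + 0.5
  nz <- length(zg); na_ <- length(ag)
  idz <- rep(seq_len(nz), each = na_)
  ang <- rep(ag, nz)
  cosA <- cos(ang * pi / 180); sinA <- sin(ang * pi / 180)
  orig <- cbind(fr$px[idz], fr$py[idz], fr$pz[idz])
  dir <- cbind(cosA * fr$e1x[idz] + sinA * fr$e2x[idz],
               cosA * fr$e1y[idz] + sinA * fr$e2y[idz],
               cosA * fr$e1z[idz] + sinA * fr$e2z[idz])
  axyz <- as.matrix(pr[, c("x", "y", "z")])
  tr <- cpp_trace_rays(orig, dir, axyz, pr$vdw_radius, voxel_size, rproj)
  hit <- tr$atom > 0
  hp <- orig + dir * ifelse(is.na(tr$t), 0, tr$t)
  out <- tibble(z = zg[idz], angle = ang, hit = hit,
                hit_atom = ifelse(hit, pr$atom[tr$atom], NA_integer_),
                hit_subunit = ifelse(hit, pr$subunit[tr$atom], NA_integer_),
                hx = ifelse(hit, hp[, 1], NA_real_),
                hy = ifelse(hit, hp[, 2], NA_real_),
                hz = ifelse(hit, hp[, 3], NA_real_))
  if (property == "mhp") {
    out$self <- out$induced <- out$total <- NA_real_
    if (any(hit)) {
      dec <- mhp_decomposed(hp[hit, , drop = FALSE], s,
                            out$hit_subunit[hit], params)
      out$self[hit] <- dec$self
      out$induced[hit] <- dec$induced
      out$total[hit] <- dec$total
    }
  } else {
    if (is.null(scores)) abort("scores required for property = 'residue_score'")
    key <- paste(s$chain_id, s$residue_number)[match(out$hit_atom, s$atom)]
    sc <- setNames(scores$score, paste(scores$chain_id, scores$residue_number))
    out$score <- unname(sc[key])
  }
  miss_rows <- out |> group_by(.data$z) |>
    summarise(all_miss = !any(.data$hit), .groups = "drop")
  structure(out, property = property, z_step = z_step,
            angle_step = angle_step, projection_radius = rproj,
            all_miss_z = miss_rows$z[miss_rows$all_miss],
            class = c("cyl_map", class(out)))
}

#' Integrate a cylindrical map over the rotation angle
#'
#' Per z row, the mean over non-miss angular nodes of each MHP component
#' (so `total = self + induced` holds at every z). Rows with no hits are
#' kept but flagged `NA`.
#'
#' @param m A `cyl_map` traced with `property = "mhp"` (any single-value map
#'   integrates its `score`/value column instead).
#' @return An `axial_profile` tibble: `z`, `self`, `induced`, `total`,
#'   `n_hit`.
#' @export
integrate_profile <- function(m) {
  if (identical(attr(m, "property"), "mhp")) {
    out <- m |> group_by(.data$z) |>
      summarise(self = mean(.data$self[.data$hit]),
                induced = mean(.data$induced[.data$hit]),
                n_hit = sum(.data$hit), .groups = "drop") |>
      mutate(total = .data$self + .data$induced)
    out <- out[, c("z", "self", "induced", "total", "n_hit")]
  } else {
    out <- m |> group_by(.data$z) |>
      summarise(score = mean(.data$score[.data$hit], na.rm = TRUE),
                n_hit = sum(.data$hit), .groups = "drop")
  }
  out[out$n_hit == 0, setdiff(names(out), c("z", "n_hit"))] <- NA_real_
  structure(out, class = c("axial_profile", class(out)))
}

#' Principal axis of a helix
#'
#' Line through the centre of mass of the helix C-alpha atoms, directed
#' along the principal axis of their mass distribution with the largest
#' principal moment (the long axis of the C-alpha cloud), with sign chosen
#' to point toward increasing global z.
#'
#' @param helix_atoms A `pore_structure` subset; only CA atoms are used.
#' @return List with `center`, unit `direction`, and the principal moments.
#' @export
helix_axis <- function(helix_atoms) {
  ca <- helix_atoms[helix_atoms$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) < 4) abort("helix_axis needs at least 4 C-alpha atoms")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) < 1e-9 * max(ev$values[1], 1))
    abort("degenerate principal axes: helix direction ill-defined")
  d <- ev$vectors[, 1]
  if (d[3] < 0) d <- -d
  list(center = ctr, direction = d, moments = ev$values)
}

# rotation matrix taking unit vector d onto +z
rotation_to_z <- function(d) {
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(d[2] * z[3] - d[3] * z[2], d[3] * z[1] - d[1] * z[3],
         d[1] * z[2] - d[2] * z[1])
  cth <- sum(d * z)
  if (sum(v^2) < 1e-16) return(diag(3) * sign(cth))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + cth))
}

rotate_structure <- function(s, R, center) {
  xyz <- as.matrix(s[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, center) %*% t(R)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

straight_axis <- function(z_range) {
  structure(tibble(x = 0, y = 0, z = z_range),
            fx = function(z, deriv = 0) if (deriv) 0 * z else 0 * z,
            fy = function(z, deriv = 0) if (deriv) 0 * z else 0 * z,
            z_range = z_range, class = c("pore_axis", "tbl_df", "tbl",
                                         "data.frame"))
}

#' Single-helix surface map with neighbour-contact mask
#'
#' Projects the self-MHP of one pore-lining helix onto the cylindrical
#' surface around its own principal axis, and marks the contact zone: every
#' surface node whose hit point lies closer than 7 Angstrom to any atom of
#' the configured neighbour residues on the other subunits.
#'
#' @param s A typed `pore_structure`.
#' @param helix_residues Residue number range (inclusive 2-vector or vector
#'   of numbers) of the mapped helix.
#' @param subunit Subunit index carrying the mapped helix (default 1).
#' @param neighbor_residues Residue numbers of the neighbouring subunits
#'   considered for contacts (e.g. 654-692 for TRPV1).
#' @param contact_dist Contact criterion distance (strictly less than;
#'   default 7 Angstrom).
#' @inheritParams trace_map
#' @return A `cyl_map` (coordinates in the helix frame: z along the helix
#'   axis) with an additional logical `contact` column.
#' @export
helix_map_with_contacts <- function(s, helix_residues, subunit = 1,
                                    neighbor_residues = NULL,
                                    contact_dist = 7,
                                    z_step = 0.5, angle_step = 2,
                                    params = mhp_params(), voxel_size = 3) {
  if (length(helix_residues) == 2) helix_residues <-
      seq(helix_residues[1], helix_residues[2])
  hx <- residue_atoms(s, helix_residues)
  hx <- hx[hx$subunit == subunit, , drop = FALSE]
  if (nrow(hx) == 0) abort("helix selection resolves to no atoms")
  ax <- helix_axis(hx)
  R <- rotation_to_z(ax$direction)
  sr <- rotate_structure(s, R, ax$center)
  hr <- sr[sr$atom %in% hx$atom, , drop = FALSE]
  zr <- range(hr$z[hr$atom_name == "CA"])
  m <- trace_map(sr, straight_axis(zr), z_step = z_step,
                 angle_step = angle_step, property = "mhp",
                 trace_atoms = hx$atom, params = params,
                 voxel_size = voxel_size)
  # contact mask in the rotated frame (distances are rotation-invariant)
  m$contact <- FALSE
  if (is.null(neighbor_residues) || length(neighbor_residues) == 0) {
    warn("empty neighbour selection: contact mask is all FALSE")
  } else {
    if (length(neighbor_residues) == 2) neighbor_residues <-
        seq(neighbor_residues[1], neighbor_residues[2])
    nb <- residue_atoms(sr, neighbor_residues)
    nb <- nb[nb$subunit != subunit, , drop = FALSE]
    if (nrow(nb) == 0) {
      warn("empty neighbour selection: contact mask is all FALSE")
    } else if (any(m$hit)) {
      pts <- as.matrix(m[m$hit, c("hx", "hy", "hz")])
      m$contact[m$hit] <- cpp_any_within(pts,
                                         as.matrix(nb[, c("x", "y", "z")]),
                                         contact_dist - 1e-9)
    }
  }
  m
}

#' Disjoint contact patches on a helix map
#'
#' Counts connected components of the contact mask on the (z, angle) grid
#' (4-neighbour connectivity, periodic in angle).
#' @param m A `cyl_map` with a `contact` column.
#' @return Integer patch count; per-node patch labels as attribute
#'   `labels`.
#' @export
contact_patches <- function(m) {
  zs <- sort(unique(m$z)); as_ <- sort(unique(m$angle))
  nz <- length(zs); na_ <- length(as_)
  g <- matrix(FALSE, nz, na_)
  g[cbind(match(m$z, zs), match(m$angle, as_))] <- m$contact
  lab <- matrix(0L, nz, na_)
  cur <- 0L
  for (i in seq_len(nz)) for (j in seq_len(na_)) {
    if (!g[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- p[1] + d[1]
        jj <- ((p[2] + d[2] - 1) %% na_) + 1  # periodic in angle
        if (ii < 1 || ii > nz) next
        if (g[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  structure(cur, labels = lab)
}
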