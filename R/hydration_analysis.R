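#' Connolly-style surface point cloud with per-point area and MHP
#'
#' Samples every protein heavy atom's probe-expanded sphere on a shared
#' deterministic lattice, rejects samples buried by neighbouring expanded
#' spheres (probe-rolling rejection) and projects the surviving samples
#' back to the van der Waals sphere. Each point carries an effective area
#' (its atom's VdW-sphere area divided by the sample count) so per-atom
#' areas partition the molecular surface, plus the MHP evaluated at the
#' point.
#'
#' @param s A typed `pore_structure`.
#' @param probe Probe radius (default 1.4 Angstrom).
#' @param density Requested points per square Angstrom (default 5); the
#'   per-atom sample count is set from the largest atom, so the realised
#'   density is at least this for every atom.
#' @param params [mhp_params()] for the per-point MHP.
#' @param mhp Set `FALSE` to skip MHP evaluation (column filled with `NA`).
#' @return A `surface_cloud` tibble: owner `atom`, `x`, `y`, `z` (on the
#'   VdW surface), `area` (A^2), `mhp`, residue identity, `subunit`.
#' @export
connolly_points <- function(s, probe = 1.4, density = 5,
                            params = mhp_params(), mhp = TRUE) {
  a <- s[s$is_protein & s$element != "H", , drop = FALSE]
  if (nrow(a) == 0) abort("no protein heavy atoms")
  key <- paste(round(a$x, 6), round(a$y, 6), round(a$z, 6),
               round(a$vdw_radius, 6))
  a <- a[!duplicated(key), , drop = FALSE]
  npts <- max(12L, as.integer(ceiling(density * 4 * pi *
                                        max(a$vdw_radius)^2)))
  res <- cpp_sphere_samples(as.matrix(a[, c("x", "y", "z")]), a$vdw_radius,
                            probe, npts)
  dirs <- res$dirs
  keep <- which(res$exposed)           # atom-major blocks of npts
  ai <- ((keep - 1L) %/% npts) + 1L
  si <- ((keep - 1L) %% npts) + 1L
  r <- a$vdw_radius[ai]
  pts <- cbind(a$x[ai] + r * dirs[si, 1],
               a$y[ai] + r * dirs[si, 2],
               a$z[ai] + r * dirs[si, 3])
  out <- tibble(atom = a$atom[ai],
                x = pts[, 1], y = pts[, 2], z = pts[, 3],
                area = 4 * pi * r^2 / npts,
                mhp = NA_real_,
                residue_name = a$residue_name[ai],
                residue_number = a$residue_number[ai],
                chain_id = a$chain_id[ai],
                subunit = a$subunit[ai])
  if (mhp) out$mhp <- mhp_at_point(pts, s, params)
  structure(out, probe = probe, n_per_atom = npts,
            class = c("surface_cloud", class(out)))
}

#' Water-exposed subset of a surface cloud
#'
#' Keeps points with at least one water oxygen within `water_dist`
#' (inclusive) and, optionally, inside an axial region.
#'
#' @param cloud A `surface_cloud`.
#' @param waters Water oxygen coordinates: an n x 3 matrix or a
#'   `pore_structure` (its water oxygens are used).
#' @param region Optional z interval `c(z0, z1)`.
#' @param water_dist Contact criterion (default 1.4 Angstrom).
#' @return The retained `surface_cloud` subset (possibly empty).
#' @export
exposed_subset <- function(cloud, waters, region = NULL, water_dist = 1.4) {
  if (inherits(waters, "data.frame")) {
    w <- waters[waters$is_water & waters$element == "O", , drop = FALSE]
    waters <- as.matrix(w[, c("x", "y", "z")])
  }
  keep <- rep(TRUE, nrow(cloud))
  if (!is.null(region)) {
    region <- sort(region)
    keep <- cloud$z >= region[1] & cloud$z <= region[2]
  }
  if (nrow(waters) == 0) return(cloud[integer(0), , drop = FALSE])
  sub <- cloud[keep, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  hit <- cpp_any_within(as.matrix(sub[, c("x", "y", "z")]), waters,
                        water_dist)
  sub[hit, , drop = FALSE]
}

# z-window between the filter and gate boundary residues (mean CA z per
# boundary residue across subunits), recomputed from the given coordinates
region_window <- function(s, region_residues) {
  lo <- residue_atoms(s, region_residues[1], atom_names = "CA")
  hi <- residue_atoms(s, region_residues[2], atom_names = "CA")
  if (nrow(lo) == 0 || nrow(hi) == 0)
    abort("region boundary residues not found")
  sort(c(mean(lo$z), mean(hi$z)))
}

#' Water-exposed surface area profile over a trajectory window
#'
#' For each frame: rebuild (or reuse) the surface cloud, select the points
#' in water contact inside the filter-to-gate region, bin their areas along
#' z and along MHP, then average over frames. `esa_hydrophobic` counts the
#' MHP > 0 share.
#'
#' @param series A `frame_series` (already windowed; see [window_frames()]).
#' @param region_residues Boundary residue pair, e.g. c(643, 682) for
#'   TRPV1's G643-M682; resolved to a z-window per frame. Alternatively a
#'   numeric z interval via `region`.
#' @param region Optional fixed z interval overriding `region_residues`.
#' @param z_bin z bin width (default 1 Angstrom).
#' @param mhp_bin MHP bin width (default 0.1 logP units).
#' @param per_frame_surface Rebuild the cloud each frame (default); if
#'   `FALSE` the topology-frame cloud is reused (static protein).
#' @inheritParams connolly_points
#' @param water_dist Water-contact criterion (1.4 Angstrom).
#' @return An `esa_profile` object: `$profile` (z, esa_total,
#'   esa_hydrophobic), `$histogram` (mhp midpoint, area), `$esa_total`,
#'   `$esa_hydrophobic` (region-integrated means), `$n_frames`.
#' @export
esa_profile <- function(series, region_residues = NULL, region = NULL,
                        z_bin = 1, mhp_bin = 0.1,
                        per_frame_surface = TRUE, probe = 1.4, density = 5,
                        params = mhp_params(), water_dist = 1.4) {
  nf <- n_frames(series)
  if (nf == 0) abort("empty frame series")
  if (is.null(region) && is.null(region_residues))
    abort("give region_residues or region")
  cloud0 <- if (!per_frame_surface)
    connolly_points(frame_structure(series, 1), probe, density, params)
  else NULL
  # common grids over the union of frame windows
  wins <- purrr::map(seq_len(nf), function(k) {
    fs <- frame_structure(series, k)
    if (!is.null(region)) sort(region) else region_window(fs, region_residues)
  })
  zr <- range(unlist(wins))
  z_edges <- seq(floor(zr[1] / z_bin) * z_bin,
                 ceiling(zr[2] / z_bin) * z_bin, by = z_bin)
  acc_t <- acc_h <- numeric(length(z_edges) - 1)
  hist_acc <- list()
  tot_t <- tot_h <- 0
  for (k in seq_len(nf)) {
    fs <- frame_structure(series, k)
    cl <- if (per_frame_surface)
      connolly_points(fs, probe, density, params) else cloud0
    ex <- exposed_subset(cl, fs, region = wins[[k]], water_dist = water_dist)
    if (nrow(ex)) {
      bz <- cut(ex$z, z_edges, include.lowest = TRUE, labels = FALSE)
      acc_t <- acc_t + tapply(ex$area, factor(bz, seq_along(acc_t)), sum,
                              default = 0)
      hyd <- ex$mhp > 0
      acc_h <- acc_h + tapply(ex$area[hyd], factor(bz[hyd],
                                                   seq_along(acc_h)),
                              sum, default = 0)
      bm <- floor(ex$mhp / mhp_bin)
      hist_acc[[k]] <- tibble(bin = bm, area = ex$area)
      tot_t <- tot_t + sum(ex$area)
      tot_h <- tot_h + sum(ex$area[hyd])
    }
  }
  prof <- tibble(z = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
                 esa_total = as.numeric(acc_t) / nf,
                 esa_hydrophobic = as.numeric(acc_h) / nf)
  hist <- bind_rows(hist_acc)
  hist <- if (nrow(hist)) hist |> group_by(.data$bin) |>
    summarise(area = sum(.data$area) / nf, .groups = "drop") |>
    mutate(mhp = (.data$bin + 0.5) * mhp_bin) |>
    select("mhp", "area") else tibble(mhp = numeric(), area = numeric())
  structure(list(profile = prof, histogram = hist,
                 esa_total = tot_t / nf, esa_hydrophobic = tot_h / nf,
                 region = zr, n_frames = nf),
            class = "esa_profile")
}

#' @export
print.esa_profile <- function(x, ...) {
  cat(sprintf(
    "<esa_profile> %d frames, region z = [%.1f, %.1f]: ESA_T = %.1f A^2, ESA_H = %.1f A^2\n",
    x$n_frames, x$region[1], x$region[2], x$esa_total, x$esa_hydrophobic))
  invisible(x)
}

replica_esa <- function(x, ...) {
  if (inherits(x, "esa_profile")) return(c(x$esa_total, x$esa_hydrophobic))
  if (inherits(x, "frame_series")) {
    p <- esa_profile(x, ...)
    return(c(p$esa_total, p$esa_hydrophobic))
  }
  abort("replicas must be esa_profile or frame_series objects")
}

#' Exposed-surface-area change between two states
#'
#' Region-integrated ESA (total and hydrophobic) per replica, difference
#' reported as state B minus state A. With equal replica counts the spread
#' is the standard deviation of the paired per-replica differences;
#' otherwise the two per-state standard deviations are propagated in
#' quadrature.
#'
#' @param replicas_a,replicas_b Lists (>= 2 each) of `esa_profile` or
#'   `frame_series` objects for states A and B.
#' @param ... Passed to [esa_profile()] when frame series are given.
#' @return Tibble with `delta_esa_total`, `delta_esa_hydrophobic`, their
#'   `sd_total`/`sd_hydrophobic`, and replica counts.
#' @export
delta_esa <- function(replicas_a, replicas_b, ...) {
  if (length(replicas_a) < 2 || length(replicas_b) < 2)
    abort("need at least 2 replicas per state")
  va <- purrr::map(replicas_a, replica_esa, ...)
  vb <- purrr::map(replicas_b, replica_esa, ...)
  ta <- purrr::map_dbl(va, 1); ha <- purrr::map_dbl(va, 2)
  tb <- purrr::map_dbl(vb, 1); hb <- purrr::map_dbl(vb, 2)
  if (length(ta) == length(tb)) {
    sdt <- sd(tb - ta); sdh <- sd(hb - ha)
  } else {
    sdt <- sqrt(sd(ta)^2 + sd(tb)^2); sdh <- sqrt(sd(ha)^2 + sd(hb)^2)
  }
  tibble(delta_esa_total = mean(tb) - mean(ta),
         delta_esa_hydrophobic = mean(hb) - mean(ha),
         sd_total = sdt, sd_hydrophobic = sdh,
         n_a = length(ta), n_b = length(tb))
}

#' Time-averaged density field and axial profile for water or ions
#'
#' 3D number density on a voxel grid covering the particles (counts per
#' frame per voxel volume; the grid integral equals the mean particle count
#' in the grid box) plus a 1D axial profile restricted to a pore cylinder:
#' mean particle count per z bin, so the profile sums to the mean count in
#' the cylinder.
#'
#' @param series A `frame_series` (window it first for "last 50 ns"-style
#'   analyses).
#' @param species `"water"` (water oxygens) or `"ion"`.
#' @param axis A `pore_axis` (used for the cylinder restriction).
#' @param voxel Grid spacing (default 1 Angstrom).
#' @param cyl_radius Pore-cylinder radius for the axial profile.
#' @param z_bin Axial bin width.
#' @return A `density_field`: `$grid` tibble (voxel centres + `density`,
#'   A^-3), `$axial` tibble (`z`, `count`), `$species`, `$n_frames`.
#' @export
density_profiles <- function(series, species = c("water", "ion"), axis,
                             voxel = 1, cyl_radius = 8, z_bin = 1) {
  species <- match.arg(species)
  top <- series$topology
  sel <- if (species == "water") which(top$is_water & top$element == "O")
         else which(top$is_ion)
  if (!length(sel)) abort(paste("no", species, "particles in topology"))
  nf <- n_frames(series)
  pts <- do.call(rbind, purrr::map(seq_len(nf), function(k)
    cbind(series$coords[sel, 1, k], series$coords[sel, 2, k],
          series$coords[sel, 3, k])))
  lo <- floor(apply(pts, 2, min) / voxel) * voxel
  hi <- ceiling(apply(pts, 2, max) / voxel + 1e-9) * voxel
  nbin <- pmax(1, round((hi - lo) / voxel))
  ix <- pmin(nbin[1], pmax(1, ceiling((pts[, 1] - lo[1]) / voxel)))
  iy <- pmin(nbin[2], pmax(1, ceiling((pts[, 2] - lo[2]) / voxel)))
  iz <- pmin(nbin[3], pmax(1, ceiling((pts[, 3] - lo[3]) / voxel)))
  cnt <- dplyr::count(tibble(ix = ix, iy = iy, iz = iz),
                      .data$ix, .data$iy, .data$iz)
  grid <- cnt |>
    mutate(x = lo[1] + (.data$ix - 0.5) * voxel,
           y = lo[2] + (.data$iy - 0.5) * voxel,
           z = lo[3] + (.data$iz - 0.5) * voxel,
           density = .data$n / nf / voxel^3) |>
    select("ix", "iy", "iz", "x", "y", "z", "density")
  # axial profile inside the pore cylinder
  fx <- attr(axis, "fx"); fy <- attr(axis, "fy")
  d2 <- (pts[, 1] - fx(pts[, 3]))^2 + (pts[, 2] - fy(pts[, 3]))^2
  inside <- d2 <= cyl_radius^2
  zin <- pts[inside, 3]
  if (length(zin)) {
    ze <- seq(floor(min(zin) / z_bin) * z_bin,
              ceiling(max(zin) / z_bin + 1e-9) * z_bin, by = z_bin)
    if (length(ze) < 2) ze <- c(ze, ze + z_bin)
    bz <- cut(zin, ze, include.lowest = TRUE, labels = FALSE)
    axial <- tibble(z = (ze[-1] + ze[-length(ze)]) / 2,
                    count = as.numeric(tapply(rep(1, length(bz)),
                                              factor(bz, seq_len(length(ze) - 1)),
                                              sum, default = 0)) / nf)
  } else {
    axial <- tibble(z = numeric(), count = numeric())
  }
  structure(list(grid = grid, axial = axial, species = species,
                 voxel = voxel, n_frames = nf),
            class = "density_field")
}

#' Count full axial crossings of a gate interval
#'
#' A crossing is a particle whose z trace passes from beyond one buffered
#' end of the interval to beyond the other (hysteresis buffers suppress
#' recrossing noise at the boundaries).
#'
#' @param series A `frame_series`.
#' @param species `"water"` or `"ion"`.
#' @param gate_z z interval `c(z0, z1)`.
#' @param buffer Hysteresis margin beyond each end (default 2 Angstrom).
#' @return Integer crossing count with per-direction attribute `directions`
#'   (`up` = increasing z, `down` = decreasing z).
#' @export
count_permeation <- function(series, species = c("water", "ion"), gate_z,
                             buffer = 2) {
  species <- match.arg(species)
  top <- series$topology
  sel <- if (species == "water") which(top$is_water & top$element == "O")
         else which(top$is_ion)
  if (!length(sel)) abort(paste("no", species, "particles in topology"))
  gate_z <- sort(gate_z)
  lo <- gate_z[1] - buffer
  hi <- gate_z[2] + buffer
  up <- down <- 0L
  for (i in sel) {
    zt <- series$coords[i, 3, ]
    zone <- ifelse(zt < lo, -1L, ifelse(zt > hi, 1L, 0L))
    zone <- zone[zone != 0L]
    if (!length(zone)) next
    flips <- diff(zone)
    up <- up + sum(flips == 2L)
    down <- down + sum(flips == -2L)
  }
  structure(up + down, directions = c(up = up, down = down))
}
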