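test_that("surface clouds conserve analytic sphere areas", {
  s <- carbon_atoms(c(0, 0, 0), f = 1)
  s$vdw_radius <- 2
  cl <- connolly_points(s, density = 5, mhp = FALSE)
  expect_lt(abs(sum(cl$area) - 4 * pi * 4) / (4 * pi * 4), 0.02)
  # doubling density ~doubles point count, area unchanged within 2%
  cl2 <- connolly_points(s, density = 10, mhp = FALSE)
  expect_gt(nrow(cl2), 1.8 * nrow(cl))
  expect_lt(nrow(cl2), 2.2 * nrow(cl))
  expect_lt(abs(sum(cl2$area) - sum(cl$area)) / sum(cl$area), 0.02)
  # two coincident identical spheres expose the same surface as one
  s2 <- carbon_atoms(rbind(c(0, 0, 0), c(0, 0, 0)), f = 1)
  s2$vdw_radius <- 2
  cl3 <- connolly_points(s2, density = 5, mhp = FALSE)
  expect_equal(sum(cl3$area), sum(cl$area), tolerance = 1e-9)
})

test_that("cloud areas are rigid-motion invariant and probe burial removes interface points", {
  s <- test_pore()
  cl <- connolly_points(s, density = 2, mhp = FALSE)
  moved <- poremapr:::apply_rot(s, poremapr:::rot_z(40))
  moved$z <- moved$z + 7
  cl2 <- connolly_points(moved, density = 2, mhp = FALSE)
  # lab-frame sampling: total area agrees within sampling noise
  expect_equal(sum(cl2$area), sum(cl$area), tolerance = 0.01)
  # buried: total is far below the sum of isolated spheres
  iso <- sum(4 * pi * s$vdw_radius[s$is_protein & s$element != "H"]^2)
  expect_lt(sum(cl$area), 0.8 * iso)
})

test_that("water-exposure selection follows the 1.4 A criterion", {
  s <- carbon_atoms(c(0, 0, 0), f = 1)
  s$vdw_radius <- 2
  cl <- connolly_points(s, density = 3, mhp = FALSE)
  # no waters: empty subset, zero area
  none <- exposed_subset(cl, matrix(numeric(), 0, 3))
  expect_equal(nrow(none), 0)
  # a water O exactly on a surface point retains it (distance 0 <= 1.4)
  w <- as.matrix(cl[1, c("x", "y", "z")])
  kept <- exposed_subset(cl, w)
  expect_gte(nrow(kept), 1)
  expect_true(any(kept$x == cl$x[1] & kept$y == cl$y[1]))
  # waters on every point saturate the selection: exposed = total area
  all_w <- as.matrix(cl[, c("x", "y", "z")])
  sat <- exposed_subset(cl, all_w)
  expect_equal(sum(sat$area), sum(cl$area))
  # axial region restriction is inclusive and exact
  half <- exposed_subset(cl, all_w, region = c(0, 3))
  expect_equal(sum(half$area), sum(cl$area[cl$z >= 0]))
})

test_that("ESA profiles average frames, split by MHP sign and conserve area", {
  s <- test_pore()
  # static protein repeated over frames with fixed waters: identical to
  # a single frame
  coords1 <- array(rep(as.matrix(s[, c("x", "y", "z")]), 1),
                   c(nrow(s), 3, 1))
  fr1 <- poremapr:::frame_series(s, coords1)
  fr3 <- poremapr:::frame_series(s, array(coords1[, , 1],
                                          c(nrow(s), 3, 3)))
  # waters: flood the lumen densely via the cloud points themselves
  cl <- connolly_points(s, density = 2)
  lum <- cl[sqrt(cl$x^2 + cl$y^2) < 6, ]
  wat <- tibble::tibble(atom_name = "O", element = "O",
                        residue_name = "HOH",
                        residue_number = seq_len(nrow(lum)),
                        chain_id = "W", x = lum$x, y = lum$y, z = lum$z)
  prot_cols <- c("atom_name", "element", "residue_name", "residue_number",
                 "chain_id", "x", "y", "z")
  top <- assign_hydrophobicity(as_structure(
    dplyr::bind_rows(s[, prot_cols], wat)), on_missing = "na")
  mk <- function(n) poremapr:::frame_series(
    top, array(rep(as.matrix(top[, c("x", "y", "z")]), n),
               c(nrow(top), 3, n)))
  e1 <- esa_profile(mk(1), region = c(2, 9), density = 2)
  e3 <- esa_profile(mk(3), region = c(2, 9), density = 2)
  expect_equal(e3$profile, e1$profile, tolerance = 1e-12)
  expect_equal(e3$esa_total, e1$esa_total, tolerance = 1e-12)
  # conservation: histogram integral equals profile integral
  expect_equal(sum(e1$histogram$area), sum(e1$profile$esa_total),
               tolerance = 1e-9)
  # hydrophobic share never exceeds the total
  expect_true(all(e1$profile$esa_hydrophobic <=
                    e1$profile$esa_total + 1e-12))
  # all-negative MHP means zero hydrophobic exposed area
  neg <- top
  neg$hydro_const <- -abs(neg$hydro_const)
  en <- esa_profile(poremapr:::frame_series(
    neg, array(as.matrix(neg[, c("x", "y", "z")]), c(nrow(neg), 3, 1))),
    region = c(2, 9), density = 2)
  expect_equal(sum(en$profile$esa_hydrophobic), 0)
  expect_gt(sum(en$profile$esa_total), 0)
})

test_that("ESA never exceeds the region surface area (saturation bound)", {
  s <- test_pore()
  fr <- make_hydrated_frames(s, n_frames = 2, water_density = 0.1, seed = 5)
  e <- esa_profile(fr, region = c(2, 9), density = 2)
  cl <- connolly_points(s, density = 2, mhp = FALSE)
  region_area <- sum(cl$area[cl$z >= 2 & cl$z <= 9])
  expect_lte(e$esa_total, region_area * 1.02)
})

test_that("dry-gate bands have zero exposed area", {
  s <- test_pore()
  fr <- make_hydrated_frames(s, n_frames = 2, water_density = 0.08,
                             dry_band = c(3, 8), seed = 9)
  e <- esa_profile(fr, region = c(3, 8), density = 2)
  # the 1.4 A water criterion can reach at most 1.4 A into the dry band,
  # so the central bin (5..6) must stay dry
  inner <- abs(e$profile$z - 5.5) < 0.01
  expect_true(any(inner))
  expect_true(all(e$profile$esa_total[inner] == 0))
})

test_that("delta ESA recovers an engineered exposed-area difference exactly", {
  s <- test_pore()
  cl <- connolly_points(s, density = 2)
  lum <- cl[sqrt(cl$x^2 + cl$y^2) < 6 & cl$z >= 2 & cl$z <= 9, ]
  band <- lum$z >= 5 & lum$z <= 7
  mk_ep <- function(keep) {
    w <- as.matrix(lum[keep, c("x", "y", "z")])
    prot_cols <- c("atom_name", "element", "residue_name", "residue_number",
                   "chain_id", "x", "y", "z")
    wat <- tibble::tibble(atom_name = "O", element = "O",
                          residue_name = "HOH",
                          residue_number = seq_len(nrow(w)), chain_id = "W",
                          x = w[, 1], y = w[, 2], z = w[, 3])
    top <- assign_hydrophobicity(as_structure(
      dplyr::bind_rows(s[, prot_cols], wat)), on_missing = "na")
    fs <- poremapr:::frame_series(
      top, array(as.matrix(top[, c("x", "y", "z")]), c(nrow(top), 3, 1)))
    esa_profile(fs, region = c(2, 9), density = 2)
  }
  dry <- mk_ep(!band)   # state A: band unwetted
  wet <- mk_ep(rep(TRUE, nrow(lum)))
  d <- delta_esa(list(dry, dry), list(wet, wet))
  # identical replicas: zero spread
  expect_equal(d$sd_total, 0)
  expect_equal(d$sd_hydrophobic, 0)
  expect_gt(d$delta_esa_total, 0)
  # oracle: brute-force 1.4 A membership against both water sets gives the
  # exact area gained (B minus A sign convention)
  wet_by <- function(wsel) {
    w <- as.matrix(lum[wsel, c("x", "y", "z")])
    apply(as.matrix(cl[, c("x", "y", "z")]), 1, function(p)
      any(sqrt(colSums((t(w) - p)^2)) <= 1.4))
  }
  in_region <- cl$z >= 2 & cl$z <= 9
  oracle <- sum(cl$area[wet_by(rep(TRUE, nrow(lum))) & in_region]) -
    sum(cl$area[wet_by(!band) & in_region])
  expect_equal(d$delta_esa_total, oracle, tolerance = 1e-9)
  d0 <- delta_esa(list(dry, dry), list(dry, dry))
  expect_equal(d0$delta_esa_total, 0)
  expect_equal(d0$sd_total, 0)
  expect_error(delta_esa(list(dry), list(wet, wet)), "at least 2")
})

test_that("density fields normalise to mean particle counts", {
  s <- test_pore()
  ax <- build_pore_axis(s, c(12, 15, 18))
  # single immobile water
  prot_cols <- c("atom_name", "element", "residue_name", "residue_number",
                 "chain_id", "x", "y", "z")
  w1 <- dplyr::bind_rows(
    s[, prot_cols],
    tibble::tibble(atom_name = "O", element = "O", residue_name = "HOH",
                   residue_number = 1, chain_id = "W", x = 0, y = 0, z = 5))
  top <- as_structure(w1)
  fs <- poremapr:::frame_series(top, array(as.matrix(top[, c("x", "y", "z")]),
                                           c(nrow(top), 3, 4)))
  d <- density_profiles(fs, "water", ax, voxel = 1)
  expect_equal(nrow(d$grid), 1)             # all mass in one voxel
  expect_equal(sum(d$grid$density) * d$voxel^3, 1)
  expect_equal(sum(d$axial$count), 1)
  expect_error(density_profiles(fs, "ion", ax), "no ion")
})

test_that("uniform particles give a flat axial profile (chi-squared)", {
  s <- test_pore()
  ax <- build_pore_axis(s, c(12, 15, 18))
  fr <- make_hydrated_frames(s, n_frames = 40, water_density = 0.05,
                             cyl_radius = 3, z_range = c(0, 10), seed = 21)
  d <- density_profiles(fr, "water", ax, cyl_radius = 5, z_bin = 1)
  counts <- d$axial$count[d$axial$z > 0.5 & d$axial$z < 9.5] * 40
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-3)
})

test_that("permeation counting requires full buffered crossings", {
  s <- test_pore()
  fr <- make_hydrated_frames(s, n_frames = 8, walk_ion = TRUE, seed = 13)
  expect_equal(as.integer(count_permeation(fr, "ion", c(4, 6))), 1L)
  expect_equal(attr(count_permeation(fr, "ion", c(4, 6)),
                    "directions")[["up"]], 1L)
  # oscillation inside the interval never counts
  top <- fr$topology
  osc <- fr
  ion_row <- which(top$is_ion)
  osc$coords[ion_row, 3, ] <- 5 + 0.4 * sin(seq_len(8))
  expect_equal(as.integer(count_permeation(osc, "ion", c(4, 6))), 0L)
  # reversed trajectories keep the count, flip the direction
  rev_fr <- poremapr:::frame_series(fr$topology,
                                    fr$coords[, , 8:1], fr$times)
  expect_equal(as.integer(count_permeation(rev_fr, "ion", c(4, 6))), 1L)
  expect_equal(attr(count_permeation(rev_fr, "ion", c(4, 6)),
                    "directions")[["down"]], 1L)
})
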