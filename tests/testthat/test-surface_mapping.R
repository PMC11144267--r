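test_that("a single on-axis sphere is hit by every ray in its z-span at its radius", {
  s <- carbon_atoms(c(0, 0, 0), f = 1)
  s$vdw_radius <- 2
  ax <- poremapr:::straight_axis(c(-1.5, 1.5))
  m <- trace_map(s, ax, z_step = 0.5, angle_step = 10)
  expect_true(all(m$hit))
  d <- sqrt(m$hx^2 + m$hy^2 + m$hz^2)
  expect_equal(d, rep(2, nrow(m)), tolerance = 1e-9)
  # the property at the hit point is constant, so the profile is constant
  p <- integrate_profile(m)
  expect_equal(p$total, rep(p$total[1], nrow(p)), tolerance = 1e-9)
})

test_that("voxel ray tracer agrees with the all-spheres oracle on >= 1000 random rays", {
  n_checked <- 0
  for (seed in 1:4) {
    s <- random_system(30, seed = seed, n_chains = 1, spread = 5)
    xyz <- as.matrix(s[, c("x", "y", "z")])
    set.seed(100 + seed)
    nr <- 300
    orig <- matrix(stats::rnorm(3 * nr, 0, 1), nr, 3)
    dir <- matrix(stats::rnorm(3 * nr), nr, 3)
    tr <- poremapr:::cpp_trace_rays(orig, dir, xyz, s$vdw_radius, 3, 1e4)
    for (q in seq_len(nr)) {
      ref <- bf_trace(orig[q, ], dir[q, ], xyz, s$vdw_radius)
      expect_identical(tr$atom[q], ref$atom)
      if (ref$atom > 0) expect_lt(abs(tr$t[q] - ref$t), 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("tracing is independent of voxel size", {
  s <- random_system(40, seed = 12, n_chains = 2, spread = 5)
  ax <- poremapr:::straight_axis(c(-4, 4))
  m1 <- trace_map(s, ax, z_step = 1, angle_step = 10, voxel_size = 2)
  m2 <- trace_map(s, ax, z_step = 1, angle_step = 10, voxel_size = 5)
  expect_identical(m1$hit_atom, m2$hit_atom)
  expect_equal(m1$total, m2$total, tolerance = 1e-12)
})

test_that("C4-symmetric maps are periodic with 90-degree period", {
  s <- test_pore()
  ax <- build_pore_axis(s, c(12, 15, 18))
  m <- trace_map(s, ax, z_step = 1, angle_step = 6, z_range = c(1, 9))
  w <- tidyr::pivot_wider(m[, c("z", "angle", "total")],
                          names_from = "angle", values_from = "total")
  v <- as.matrix(w[, -1])
  k <- 90 / 6
  expect_lt(max(abs(v - v[, c((k + 1):ncol(v), 1:k)]), na.rm = TRUE), 1e-9)
})

test_that("angular integration yields additive self/induced/total profiles", {
  s <- test_pore()
  ax <- build_pore_axis(s, c(12, 15, 18))
  m <- trace_map(s, ax, z_step = 1, angle_step = 10, z_range = c(0, 10))
  p <- integrate_profile(m)
  expect_equal(p$total, p$self + p$induced, tolerance = 1e-12)
  # angle-origin rotation invariance for C4 input: shift the angular grid
  m2 <- trace_map(poremapr:::apply_rot(s, poremapr:::rot_z(90)), ax,
                  z_step = 1, angle_step = 10, z_range = c(0, 10))
  p2 <- integrate_profile(m2)
  expect_equal(p$total, p2$total, tolerance = 1e-9)
})

test_that("rows with no surrounding atoms are flagged as misses", {
  s <- carbon_atoms(c(0, 0, 0))
  s$vdw_radius <- 2
  ax <- poremapr:::straight_axis(c(-1, 30))
  m <- trace_map(s, ax, z_step = 31, angle_step = 30)
  expect_true(30 %in% attr(m, "all_miss_z"))
  p <- integrate_profile(m)
  expect_true(is.na(p$total[p$z == 30]))
})

test_that("helix_axis finds the long axis, equivariantly under rotation", {
  h <- build_peptide(rep("ALA", 12))
  ax <- helix_axis(h)
  hz <- poremapr:::rotate_structure(h, poremapr:::rotation_to_z(ax$direction),
                                    ax$center)
  az <- helix_axis(hz)
  expect_gt(abs(az$direction[3]), cos(1 * pi / 180))  # within 1 deg of z
  R <- poremapr:::rot_z(25) %*% matrix(c(1, 0, 0, 0, cos(.5), -sin(.5),
                                         0, sin(.5), cos(.5)), 3, 3,
                                       byrow = TRUE)
  hr <- poremapr:::apply_rot(hz, R)
  ar <- helix_axis(hr)
  expect_equal(abs(sum(ar$direction * (R %*% az$direction))), 1,
               tolerance = 1e-6)
  expect_error(helix_axis(h[h$residue_number <= 3, ]), "at least 4")
})

test_that("helix contact masks follow the strict 7 A criterion", {
  s <- test_pore()
  # neighbours absent -> all-false mask with a warning
  expect_warning(m0 <- helix_map_with_contacts(s, c(10, 20), subunit = 1,
                                               neighbor_residues = NULL),
                 "empty neighbour")
  expect_false(any(m0$contact))
  # real neighbours: the helix touches its two flanking subunits
  m <- helix_map_with_contacts(s, c(10, 20), subunit = 1,
                               neighbor_residues = c(1, 22))
  expect_true(any(m$contact))
  expect_true(all(m$hit[m$contact]))
})

test_that("a neighbour atom at 6.9 A marks a node; at 7.1 A it does not", {
  # one sphere to map, one neighbour atom placed at a known distance from
  # the surface point at angle 0
  s <- carbon_atoms(rbind(c(0, 0, 0), c(2 + 6.9, 0, 0)), f = 1,
                    chain = c("A", "B"))
  s$vdw_radius[1] <- 2
  sm <- s
  sm$residue_number <- c(5, 50)
  m <- helix_contact_probe(sm)
  node0 <- m[m$hit & abs(m$angle - 0) < 1e-9 & abs(m$z) < 0.26, ]
  expect_true(all(node0$contact))
  far <- sm
  far$x[2] <- 2 + 7.1
  m2 <- helix_contact_probe(far)
  expect_false(any(m2$contact))
})

test_that("engineered two-zone neighbours give two disjoint contact patches", {
  s <- test_pore()
  m <- helix_map_with_contacts(s, c(10, 20), subunit = 1,
                               neighbor_residues = c(1, 22))
  expect_equal(as.integer(contact_patches(m)), 2L)
})
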