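ca_quad <- function(resno, a, z, chains = c("A", "B", "C", "D")) {
  tibble::tibble(atom_name = "CA", element = "C", residue_name = "GLY",
                 residue_number = resno, chain_id = chains,
                 x = c(a, 0, -a, 0), y = c(0, a, 0, -a), z = z)
}

test_that("axis control points are quadruplet centres of mass and C4 axes are straight", {
  s <- as_structure(dplyr::bind_rows(ca_quad(1, 4, 0), ca_quad(2, 4, 5)))
  ax <- build_pore_axis(s, c(1, 2))
  expect_equal(ax$x, c(0, 0), tolerance = 1e-12)
  expect_equal(ax$y, c(0, 0), tolerance = 1e-12)
  expect_equal(ax$z, c(0, 5))

  pore <- test_pore()
  axp <- build_pore_axis(pore, c(8, 12, 15, 18))
  fr <- axis_frame(axp, seq(min(axp$z), max(axp$z), length.out = 25))
  expect_lt(max(abs(fr$px), abs(fr$py)), 1e-6)   # collinear with z axis

  # residue missing in one subunit
  s3 <- as_structure(dplyr::bind_rows(ca_quad(1, 4, 0), ca_quad(2, 4, 5),
                                      ca_quad(3, 4, 9)[1:3, ]))
  expect_error(build_pore_axis(s3, c(1, 2, 3)), "missing in some subunits")
  expect_error(build_pore_axis(s, c(1, 2, 99)), "absent")
})

test_that("four-sphere ring gives the closed-form pore radius", {
  ring <- carbon_atoms(rbind(c(4, 0, 2), c(0, 4, 2), c(-4, 0, 2), c(0, -4, 2)),
                       vdw = 1.7)
  axis_atoms <- as_structure(dplyr::bind_rows(ca_quad(90, 30, 0),
                                              ca_quad(91, 30, 4)))
  s <- as_structure(dplyr::bind_rows(
    ring[, c("atom_name", "element", "residue_name", "residue_number",
             "chain_id", "x", "y", "z")],
    axis_atoms[, c("atom_name", "element", "residue_name", "residue_number",
                   "chain_id", "x", "y", "z")]))
  s$vdw_radius[1:4] <- 1.7
  ax <- build_pore_axis(s, c(90, 91))
  prof <- radius_profile(s, ax, z_step = 0.25, z_range = c(2, 2))
  expect_equal(prof$radius, 4.0 - 1.7, tolerance = 1e-4)
})

test_that("optimised radius matches a dense brute-force centre search on random systems", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30
    th <- stats::runif(n, 0, 2 * pi)
    rr <- stats::runif(n, 3.5, 6)
    xyz <- cbind(rr * cos(th), rr * sin(th), stats::runif(n, -2, 2))
    s <- carbon_atoms(xyz, vdw = stats::runif(n, 1.2, 1.9))
    ax <- poremapr:::straight_axis(c(-1, 1))
    prof <- radius_profile(s, ax, z_step = 1, z_range = c(-1, 1),
                           max_disp = 2)
    for (k in seq_len(nrow(prof))) {
      ref <- bf_plane_radius(c(0, 0, prof$z[k]), c(1, 0, 0), c(0, 1, 0),
                             as.matrix(s[, c("x", "y", "z")]), s$vdw_radius,
                             max_disp = 2, step = 0.02)
      expect_lt(abs(prof$radius[k] - ref), 0.05)
    }
  }
})

test_that("uniform VdW inflation shifts the radius profile by exactly the inflation", {
  ring <- carbon_atoms(rbind(c(4, 0, 0), c(0, 4, 0), c(-4, 0, 0),
                             c(0, -4, 0)), vdw = 1.5)
  ax <- poremapr:::straight_axis(c(-0.5, 0.5))
  r1 <- radius_profile(ring, ax, z_step = 0.5, z_range = c(0, 0))$radius
  ring$vdw_radius <- ring$vdw_radius + 0.3
  r2 <- radius_profile(ring, ax, z_step = 0.5, z_range = c(0, 0))$radius
  expect_equal(r1 - r2, 0.3, tolerance = 1e-5)
})

test_that("synthetic pores recover their target lumen radius within 0.1 A", {
  for (target in c(2.0, 2.3, 3.0)) {
    s <- make_c4_pore(pore_spec(lumen_radius = target))
    ax <- build_pore_axis(s, c(12, 15, 18))
    prof <- radius_profile(s, ax, z_step = 0.25)
    expect_lt(abs(min(prof$radius) - target), 0.1)
  }
})

test_that("gate_radius takes the exact regional minimum with documented tie-break", {
  prof <- structure(tibble::tibble(z = seq(0, 10, 0.5),
                                   radius = seq(5, 0, length.out = 21),
                                   capped = FALSE, converged = TRUE),
                    class = c("radius_profile", "tbl_df", "tbl",
                              "data.frame"))
  expect_equal(as.numeric(gate_radius(prof, c(0, 4))),
               prof$radius[prof$z == 4])  # monotone: boundary value
  # two equal minima: minimum value, first (smallest z) position reported
  prof$radius <- c(rep(2, 10), 1, rep(3, 9), 1)
  expect_equal(as.numeric(gate_radius(prof, c(0, 10))), 1)
  expect_equal(attr(gate_radius(prof, c(0, 10)), "z_min"), 5)
  expect_error(gate_radius(prof, c(50, 60)), "no profile points")
})

test_that("sections without nearby atoms are capped and flagged", {
  ring <- carbon_atoms(rbind(c(4, 0, 0), c(0, 4, 0), c(-4, 0, 0),
                             c(0, -4, 0)), vdw = 1.5)
  ax <- poremapr:::straight_axis(c(0, 60))
  prof <- radius_profile(ring, ax, z_step = 30, z_range = c(0, 60),
                         max_radius = 10)
  expect_true(all(prof$capped[prof$z == 60]))
  expect_equal(prof$radius[prof$z == 60], 10)
})
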