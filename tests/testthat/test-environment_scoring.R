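# carbon (or oxygen) cage fully enclosing the origin at the given radius
cage_atoms <- function(radius = 5, n = 200, element = "C", chain = "B") {
  u <- poremapr:::cpp_fibonacci_sphere(as.integer(n))
  el_name <- if (element == "C") "CB" else "OD1"
  resn <- if (element == "C") "ALA" else "ASP"
  tibble::tibble(atom_name = el_name, element = element,
                 residue_name = resn, residue_number = seq_len(n) + 100,
                 chain_id = chain,
                 x = radius * u[, 1], y = radius * u[, 2],
                 z = radius * u[, 3])
}

centre_residue <- function(resn = "LEU") {
  sc <- poremapr:::sidechain_atoms(resn)
  nm <- c("N", "CA", "C", "O", sc$names)
  el <- c("N", "C", "C", "O", sc$elements)
  k <- length(nm)
  set.seed(42)
  xyz <- matrix(stats::rnorm(3 * k, 0, 0.8), k, 3)
  tibble::tibble(atom_name = nm, element = el, residue_name = resn,
                 residue_number = 1, chain_id = "A",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("fully exposed residues class as E regardless of polarity", {
  h <- build_peptide(rep(c("LEU", "ASN", "SER", "ILE"), 4))
  env <- residue_environment(h, 2:15)
  expect_true(all(env$env_class == "E"))
  expect_true(all(env$secondary == "helix"))
})

test_that("a residue enclosed by apolar atoms classes buried-apolar, by polar atoms buried-polar", {
  apolar <- as_structure(dplyr::bind_rows(centre_residue("LEU"),
                                          cage_atoms(element = "C")))
  env <- residue_environment(apolar, 1, chain = "A")
  expect_equal(env$env_class, "B1")
  expect_gt(env$buried_area, environment_thresholds()$buried_hi)
  polar <- as_structure(dplyr::bind_rows(centre_residue("LEU"),
                                         cage_atoms(element = "O")))
  env2 <- residue_environment(polar, 1, chain = "A")
  expect_equal(env2$env_class, "B3")
  expect_gt(env2$polar_fraction, environment_thresholds()$b_breaks[2])
})

test_that("environments are invariant to file atom order and rigid motion", {
  s <- test_pore()
  env <- residue_environment(s, 12:16, chain = "A")
  set.seed(3)
  perm <- s[sample(nrow(s)), ]
  env_p <- residue_environment(as_structure(perm[, c(
    "atom_name", "element", "residue_name", "residue_number", "chain_id",
    "x", "y", "z")]), 12:16, chain = "A")
  expect_equal(env_p[order(env_p$residue_number), ]$env_class,
               env[order(env$residue_number), ]$env_class)
  moved <- poremapr:::apply_rot(s, poremapr:::rot_z(63))
  moved$x <- moved$x + 11; moved$z <- moved$z - 4
  env_m <- residue_environment(moved, 12:16, chain = "A")
  # areas from finite lab-frame sphere sampling: equal within sampling noise
  expect_equal(env_m$buried_area, env$buried_area, tolerance = 0.15)
  expect_equal(env_m$env_class, env$env_class)
})

test_that("scores are pure lookups: same residue and class give the same score", {
  tab <- score_table()
  s <- test_pore()
  p1 <- score_profile(s, c(10, 18), state = "a")
  p2 <- score_profile(s, c(10, 18), state = "b")
  expect_identical(p1$score, p2$score)
  # direct lookup agreement
  env <- residue_environment(s, 15, chain = "A")
  want <- tab$score[tab$residue == env$residue_name &
                      tab$env_class == env$env_class &
                      tab$secondary == env$secondary]
  one <- score_profile(s, 15, chain = "A")
  expect_equal(one$score, want)
  expect_identical(attr(p1, "score_table"), "synthetic-v1")
})

test_that("profile correlations satisfy self = 1, mean-negation = -1", {
  s <- test_pore()
  p <- score_profile(s, c(8, 20))
  expect_equal(profile_correlation(p, p), 1.0)
  neg <- p
  neg$score <- 2 * mean(p$score) - p$score
  expect_equal(profile_correlation(p, neg), -1.0)
  flat <- p
  flat$score <- rep(1, nrow(p))
  expect_error(profile_correlation(p, flat), "zero variance")
  expect_error(profile_correlation(p[1:2, ], p[1:2, ]), "fewer than 3")
})

test_that("alignment maps translate residue numbering across channels", {
  s <- test_pore()
  p1 <- score_profile(s, c(8, 20), channel = "chanA")
  shifted <- s
  shifted$residue_number <- shifted$residue_number + 100
  p2 <- score_profile(shifted, c(108, 120), channel = "chanB")
  map <- tibble::tibble(chanA = 8:20, chanB = 108:120)
  expect_equal(profile_correlation(p1, p2, map), 1.0)
  # shipped TRPV alignment has the documented shape
  al <- s6_alignment()
  expect_named(al, c("trpv1", "trpv3", "trpv6"))
  expect_equal(al$trpv1 - al$trpv3, rep(5, nrow(al)))
  expect_equal(al$trpv1 - al$trpv6, rep(104, nrow(al)))
})

test_that("correlation matrices are symmetric with unit diagonal", {
  s <- test_pore()
  p <- score_profile(s, c(8, 20))
  q <- p; set.seed(8); q$score <- q$score + stats::rnorm(nrow(q), 0, 0.2)
  m <- correlation_matrix(list(a = p, b = q, c = p))
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "c"], 1)
  m3 <- correlation_matrix(list(p, p, p))
  expect_true(all(m3 == 1))
  expect_error(correlation_matrix(list(p)), "at least 2")
})
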