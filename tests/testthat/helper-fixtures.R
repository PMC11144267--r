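# fixtures and independent oracles, built in code

# a bag of carbon pseudo-atoms (typed, hydro_const = f) at given coordinates
carbon_atoms <- function(xyz, f = 1, chain = "A", vdw = 1.7) {
  xyz <- matrix(xyz, ncol = 3)
  s <- as_structure(tibble::tibble(
    atom_name = "CB", element = "C", residue_name = "ALA",
    residue_number = seq_len(nrow(xyz)), chain_id = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  s$vdw_radius <- vdw
  s$hydro_const <- rep_len(f, nrow(xyz))
  s
}

# random typed atom cloud, multiple chains
random_system <- function(n, seed, n_chains = 2, spread = 6) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, 0, spread), n, 3)
  s <- as_structure(tibble::tibble(
    atom_name = "CB", element = "C", residue_name = "ALA",
    residue_number = seq_len(n),
    chain_id = LETTERS[rep_len(seq_len(n_chains), n)],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  s$hydro_const <- stats::runif(n, -1, 1)
  s
}

# brute-force MHP: direct sum over all atoms, hard cutoff
bf_mhp <- function(p, s, rcut = 9, decay = 2) {
  a <- s[s$is_protein, ]
  r <- sqrt((a$x - p[1])^2 + (a$y - p[2])^2 + (a$z - p[3])^2)
  sum(a$hydro_const[r < rcut] * exp(-r[r < rcut] / decay))
}

# brute-force nearest ray-sphere intersection over all atoms
bf_trace <- function(o, d, xyz, radii) {
  d <- d / sqrt(sum(d^2))
  best <- Inf; who <- 0L
  for (i in seq_len(nrow(xyz))) {
    oc <- o - xyz[i, ]
    b <- sum(oc * d)
    cc <- sum(oc^2) - radii[i]^2
    disc <- b^2 - cc
    if (disc < 0) next
    t <- -b - sqrt(disc)
    if (t < 0) t <- -b + sqrt(disc)
    if (t >= 0 && t < best) { best <- t; who <- i }
  }
  list(atom = who, t = if (is.finite(best)) best else NA_real_)
}

# brute-force largest clear sphere: dense grid over in-plane displacements
bf_plane_radius <- function(p0, e1, e2, xyz, radii, max_disp = 5,
                            step = 0.02) {
  g <- seq(-max_disp, max_disp, by = step)
  best <- -Inf
  for (u in g) for (v in g) {
    if (u * u + v * v > max_disp^2) next
    c0 <- p0 + u * e1 + v * e2
    d <- sqrt((xyz[, 1] - c0[1])^2 + (xyz[, 2] - c0[2])^2 +
              (xyz[, 3] - c0[3])^2) - radii
    m <- min(d)
    if (m > best) best <- m
  }
  best
}

# minimal PDB text writer for hand-crafted parsing cases
pdb_line <- function(serial, name, resn, chain, resno, x, y, z, occ = 1,
                     alt = " ", el = "C") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, el)
}

# small alpha-helical test pore shared across files (cached per session)
test_pore <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_c4_pore(pore_spec(lumen_radius = 2.3))
    cache
  }
})

# trace a map over atom 1 of `s` and mark contacts against atom 2 (other
# chain), used to probe the 7 A criterion with exact geometry
helix_contact_probe <- function(s, contact_dist = 7) {
  ax <- poremapr:::straight_axis(c(-0.25, 0.25))
  m <- trace_map(s, ax, z_step = 0.25, angle_step = 10,
                 trace_atoms = s$atom[1])
  nb <- as.matrix(s[2, c("x", "y", "z")])
  m$contact <- FALSE
  if (any(m$hit))
    m$contact[m$hit] <- poremapr:::cpp_any_within(
      as.matrix(m[m$hit, c("hx", "hy", "hz")]), nb, contact_dist - 1e-9)
  m
}
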