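#' MHP evaluation parameters
#'
#' The molecular hydrophobicity potential at a point j is the superposition
#' of attenuated atomic contributions \eqn{\sum_i f_i \exp(-r_{ij}/2)}, with
#' a hard cutoff: only atoms closer than `r_cut` = 9 Angstrom contribute
#' (the contribution is identically zero at and beyond the cutoff; no
#' shifting or smoothing). Values are on the octanol-water logP scale.
#'
#' @param decay_length Denominator of the exponential attenuation (Angstrom).
#' @param r_cut Hard distance cutoff (Angstrom).
#' @export
mhp_params <- function(decay_length = 2, r_cut = 9) {
  stopifnot(r_cut > 0, decay_length > 0)
  list(decay_length = decay_length, r_cut = r_cut)
}

# per-subunit MHP contributions at a set of points; protein atoms only,
# every contributing atom must be typed
mhp_contrib_matrix <- function(points, s, params) {
  pr <- protein_xyz(s)
  if (anyNA(pr$f)) abort("unassigned hydrophobicity constants; run assign_hydrophobicity() first")
  pts <- matrix(as.numeric(points), ncol = 3)
  cpp_mhp_contrib(pts, pr$xyz, pr$f, as.integer(pr$subunit),
                  as.integer(pr$n_subunits), params$r_cut,
                  params$decay_length)
}

#' Molecular hydrophobicity potential at points
#'
#' @param points Numeric 3-vector or n x 3 matrix of evaluation points.
#' @param s A typed `pore_structure` (see [assign_hydrophobicity()]); only
#'   protein atoms contribute (waters/ions/lipids never enter MHP sums).
#' @param params [mhp_params()].
#' @return Numeric vector of MHP values (octanol-water logP units).
#' @export
mhp_at_point <- function(points, s, params = mhp_params()) {
  rowSums(mhp_contrib_matrix(points, s, params))
}

#' Self/induced/total MHP decomposition
#'
#' Splits the MHP at each point into the contribution of the owner subunit
#' (self) and of all other protein subunits (induced). The two parts sum to
#' the total exactly (same summation, partitioned by subunit).
#'
#' @inheritParams mhp_at_point
#' @param owner_subunit Owner subunit index (1-based), scalar or per point.
#' @return Tibble with `self`, `induced`, `total`.
#' @export
mhp_decomposed <- function(points, s, owner_subunit, params = mhp_params()) {
  m <- mhp_contrib_matrix(points, s, params)
  owner <- as.integer(owner_subunit)
  if (any(is.na(owner)) || any(owner < 1 | owner > ncol(m)))
    abort("owner_subunit out of range")
  if (length(owner) == 1) owner <- rep(owner, nrow(m))
  if (length(owner) != nrow(m)) abort("owner_subunit length mismatch")
  self <- m[cbind(seq_len(nrow(m)), owner)]
  induced <- vapply(seq_len(nrow(m)), function(i)
    sum(m[i, -owner[i]]), numeric(1))
  # total is defined as self + induced so the decomposition is exact
  tibble(self = self, induced = induced, total = self + induced)
}
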