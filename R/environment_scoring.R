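BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
POLAR_ELEMENTS <- c("N", "O")

canonical_aa <- function(residue_name) {
  rn <- toupper(residue_name)
  rn[rn == "MSE"] <- "MET"
  rn[rn %in% c("HSD", "HSE", "HSP", "HID", "HIE", "HIP")] <- "HIS"
  rn
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples each atom's probe-expanded sphere on a deterministic Fibonacci
#' lattice; the accessible area is the exposed sample fraction times the
#' expanded-sphere area. Buried samples record their deepest blocking atom,
#' which supports the polar-fraction bookkeeping of the residue-environment
#' classes.
#'
#' @param s A `pore_structure`.
#' @param probe Probe radius (default 1.4 Angstrom, a water molecule).
#' @param n_points Samples per atom.
#' @param include_waters Include water oxygens as blockers (they are never
#'   reported themselves). Default `FALSE`: accessibility is computed for
#'   the desolvated assembly.
#' @return Tibble per protein heavy atom: `atom`, `sasa` (A^2), number of
#'   buried samples, number of buried samples blocked by polar (N/O) atoms,
#'   and the sample weight `area_per_point`.
#' @export
sasa_atoms <- function(s, probe = 1.4, n_points = 242,
                       include_waters = FALSE) {
  sel <- s$is_protein & s$element != "H"
  if (include_waters) sel <- sel | (s$is_water & s$element == "O")
  a <- s[sel, , drop = FALSE]
  if (nrow(a) == 0) abort("no atoms for SASA")
  # coincident duplicates (same centre and radius) would spuriously bury
  # each other; keep the first
  key <- paste(round(a$x, 6), round(a$y, 6), round(a$z, 6),
               round(a$vdw_radius, 6))
  a <- a[!duplicated(key), , drop = FALSE]
  res <- cpp_sphere_samples(as.matrix(a[, c("x", "y", "z")]), a$vdw_radius,
                            probe, as.integer(n_points))
  expo <- matrix(res$exposed, nrow = n_points)   # samples x atoms
  blk <- matrix(res$blocker, nrow = n_points)
  polar_blk <- matrix(FALSE, nrow(blk), ncol(blk))
  polar_blk[blk > 0] <- a$element[blk[blk > 0]] %in% POLAR_ELEMENTS
  out <- tibble(atom = a$atom,
                element = a$element,
                residue_name = a$residue_name,
                residue_number = a$residue_number,
                chain_id = a$chain_id,
                atom_name = a$atom_name,
                is_protein = a$is_protein,
                n_exposed = colSums(expo),
                n_buried = n_points - colSums(expo),
                n_polar_buried = colSums(polar_blk),
                area_per_point = 4 * pi * (a$vdw_radius + probe)^2 / n_points)
  out$sasa <- out$n_exposed * out$area_per_point
  out[out$is_protein, , drop = FALSE]
}

side_chain_rows <- function(sasa_tab) {
  sc <- !(sasa_tab$atom_name %in% BACKBONE_ATOMS)
  # glycine has no heavy side chain: use CA as its stand-in
  sc[toupper(sasa_tab$residue_name) == "GLY" & sasa_tab$atom_name == "CA"] <- TRUE
  sasa_tab[sc, , drop = FALSE]
}

# reference side-chain accessibility: residue X in an extended Gly-X-Gly
# tripeptide built with the package's own peptide builder, same radii,
# probe and sampling as the query. Cached per (probe, n_points).
reference_sidechain_area <- function(probe = 1.4, n_points = 242) {
  key <- sprintf("refarea_%g_%d", probe, n_points)
  if (!is.null(.pm_env[[key]])) return(.pm_env[[key]])
  aa <- sort(unique(canonical_aa(hydrophobicity_table()$residue)))
  ref <- purrr::map_dbl(aa, function(x) {
    pep <- build_peptide(c("GLY", x, "GLY"), phi = -120, psi = 120)
    tab <- side_chain_rows(sasa_atoms(pep, probe, n_points))
    sum(tab$sasa[tab$residue_number == 2])
  })
  .pm_env[[key]] <- setNames(ref, aa)
  .pm_env[[key]]
}

#' Residue environment descriptors and class
#'
#' For each requested residue, the buried side-chain area (reference
#' extended-state accessibility minus observed accessibility in the full
#' assembly), the polar fraction of the buried surface (area share of
#' buried samples whose blocker is N/O), the secondary structure from the
#' backbone hydrogen-bond pattern, and the resulting environment class
#' (B1/B2/B3/P1/P2/E crossed with helix/sheet/other; thresholds from
#' [environment_thresholds()]).
#'
#' @param s A `pore_structure`.
#' @param residues Residue numbers to describe.
#' @param chain Optional chain restriction.
#' @param probe,n_points,include_waters Passed to [sasa_atoms()].
#' @return Tibble: `chain_id`, `residue_number`, `residue_name`,
#'   `buried_area`, `polar_fraction`, `secondary`, `env_class`.
#' @export
residue_environment <- function(s, residues, chain = NULL, probe = 1.4,
                                n_points = 242, include_waters = FALSE) {
  tab <- sasa_atoms(s, probe, n_points, include_waters)
  sc <- side_chain_rows(tab)
  ss <- secondary_structure(s)
  ref <- reference_sidechain_area(probe, n_points)
  env <- sc |>
    group_by(.data$chain_id, .data$residue_number, .data$residue_name) |>
    summarise(obs_area = sum(.data$sasa),
              buried_samples_area = sum(.data$n_buried * .data$area_per_point),
              polar_samples_area = sum(.data$n_polar_buried *
                                         .data$area_per_point),
              .groups = "drop")
  env <- env[env$residue_number %in% residues, , drop = FALSE]
  if (!is.null(chain)) env <- env[env$chain_id %in% chain, , drop = FALSE]
  if (nrow(env) == 0) abort("no resolvable residues in selection")
  aa <- canonical_aa(env$residue_name)
  bad <- !(aa %in% names(ref))
  if (any(bad)) abort(paste("cannot resolve environment for residues:",
                            paste(unique(env$residue_name[bad]),
                                  collapse = ", ")))
  env$buried_area <- pmax(0, ref[aa] - env$obs_area)
  env$polar_fraction <- ifelse(env$buried_samples_area > 0,
                               env$polar_samples_area /
                                 env$buried_samples_area, 0)
  env <- left_join(env, ss, by = c("chain_id", "residue_number"))
  env$secondary[is.na(env$secondary)] <- "other"
  env$env_class <- classify_environment(env$buried_area, env$polar_fraction)
  env |> select("chain_id", "residue_number", "residue_name",
                "buried_area", "polar_fraction", "secondary", "env_class")
}

#' @rdname residue_environment
#' @param buried_area,polar_fraction Numeric vectors.
#' @export
classify_environment <- function(buried_area, polar_fraction) {
  th <- environment_thresholds()
  dplyr::case_when(
    buried_area < th$buried_lo ~ "E",
    buried_area < th$buried_hi & polar_fraction < th$p_break ~ "P1",
    buried_area < th$buried_hi ~ "P2",
    polar_fraction < th$b_breaks[1] ~ "B1",
    polar_fraction < th$b_breaks[2] ~ "B2",
    TRUE ~ "B3")
}

#' Per-residue 3D-1D environment score profile
#'
#' Looks up the compatibility score of each residue's amino acid with its
#' environment class. Higher scores mean a more favourable environment.
#' Missing residues are absent from the output (never zero-filled). Scores
#' from multiple subunits are averaged per residue number unless a chain is
#' given.
#'
#' @inheritParams residue_environment
#' @param state,channel Optional labels carried in the result.
#' @param table Score table (default the shipped synthetic surrogate; the
#'   table id is recorded in the `score_table` attribute).
#' @return A `score_profile` tibble: `residue_number`, `residue_name`,
#'   `score`, `n_chains`.
#' @export
score_profile <- function(s, residues, chain = NULL, state = NULL,
                          channel = NULL, table = score_table(),
                          probe = 1.4, n_points = 242,
                          include_waters = FALSE) {
  if (length(residues) == 2 && residues[2] > residues[1] + 1)
    residues <- seq(residues[1], residues[2])
  env <- residue_environment(s, residues, chain, probe, n_points,
                             include_waters)
  key <- paste(canonical_aa(env$residue_name), env$env_class, env$secondary)
  lut <- setNames(table$score,
                  paste(table$residue, table$env_class, table$secondary))
  env$score <- unname(lut[key])
  out <- env |>
    group_by(.data$residue_number) |>
    summarise(residue_name = first(.data$residue_name),
              score = mean(.data$score), n_chains = n(), .groups = "drop") |>
    arrange(.data$residue_number)
  structure(out, state = state, channel = channel,
            score_table = attr(table, "score_table_id") %||% "custom",
            class = c("score_profile", class(out)))
}

align_positions <- function(a, b, map = NULL) {
  if (is.null(map)) {
    pos_a <- a$residue_number
    pos_b <- b$residue_number
    common <- intersect(pos_a, pos_b)
    return(list(a = a$score[match(common, pos_a)],
                b = b$score[match(common, pos_b)]))
  }
  ca <- attr(a, "channel"); cb <- attr(b, "channel")
  if (is.null(ca) || is.null(cb) || !all(c(ca, cb) %in% names(map)))
    abort("profiles need 'channel' labels matching the alignment columns")
  ia <- match(map[[ca]], a$residue_number)
  ib <- match(map[[cb]], b$residue_number)
  ok <- !is.na(ia) & !is.na(ib)
  list(a = a$score[ia[ok]], b = b$score[ib[ok]])
}

#' Pearson correlation of two aligned 3D-1D score profiles
#'
#' Positions are matched through the alignment map (or by residue number
#' when `map` is `NULL`); positions missing on either side are dropped
#' pairwise.
#'
#' @param a,b `score_profile` objects.
#' @param map Optional alignment tibble whose columns are channel keys and
#'   rows aligned residue numbers (see [s6_alignment()]).
#' @return Pearson R.
#' @export
profile_correlation <- function(a, b, map = NULL) {
  al <- align_positions(a, b, map)
  ok <- !is.na(al$a) & !is.na(al$b)
  if (sum(ok) < 3) abort("fewer than 3 aligned scored positions")
  if (sd(al$a[ok]) == 0 || sd(al$b[ok]) == 0)
    abort("zero variance in a score profile")
  cor(al$a[ok], al$b[ok])
}

#' Pairwise correlation matrix of score profiles
#'
#' @param profiles Named list of `score_profile` objects.
#' @param map Optional alignment map (see [profile_correlation()]).
#' @return Symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(profiles, map = NULL) {
  n <- length(profiles)
  if (n < 2) abort("need at least 2 profiles")
  nm <- names(profiles) %||% paste0("profile", seq_len(n))
  m <- diag(1, n)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    r <- profile_correlation(profiles[[i]], profiles[[j]], map)
    m[i, j] <- m[j, i] <- r
  }
  m
}
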