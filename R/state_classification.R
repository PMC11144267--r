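#' Backbone hydrogen bonds (DSSP-style electrostatic criterion)
#'
#' Amide hydrogens are placed geometrically (1.0 Angstrom from N, anti to
#' the preceding carbonyl), and the Kabsch-Sander electrostatic energy
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol is
#' evaluated for donor/acceptor residue pairs; pairs with E below the
#' cutoff count as hydrogen bonds. Prolines and chain-initial residues
#' cannot donate.
#'
#' @param s A `pore_structure` with backbone N, CA, C, O atoms.
#' @param e_cut Energy cutoff (default -0.5 kcal/mol).
#' @param max_ca_dist Donor/acceptor CA prefilter distance.
#' @return Tibble: donor `chain_id`/`residue_number`, acceptor
#'   `chain_id_acc`/`residue_number_acc`, `energy`, and the sequence
#'   separation `sep` (acceptor to donor, `NA` across chains).
#' @export
backbone_hbonds <- function(s, e_cut = -0.5, max_ca_dist = 9) {
  p <- s[s$is_protein & s$atom_name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  res <- p |>
    group_by(.data$chain_id, .data$residue_number) |>
    summarise(residue_name = first(.data$residue_name),
              nx = .data$x[match("N", .data$atom_name)],
              ny = .data$y[match("N", .data$atom_name)],
              nz = .data$z[match("N", .data$atom_name)],
              cax = .data$x[match("CA", .data$atom_name)],
              cay = .data$y[match("CA", .data$atom_name)],
              caz = .data$z[match("CA", .data$atom_name)],
              cx = .data$x[match("C", .data$atom_name)],
              cy = .data$y[match("C", .data$atom_name)],
              cz = .data$z[match("C", .data$atom_name)],
              ox = .data$x[match("O", .data$atom_name)],
              oy = .data$y[match("O", .data$atom_name)],
              oz = .data$z[match("O", .data$atom_name)],
              .groups = "drop") |>
    arrange(.data$chain_id, .data$residue_number)
  if (anyNA(res[, c("nx", "cax", "cx", "ox")]))
    abort("missing backbone atoms (need N, CA, C, O per residue)")
  n <- nrow(res)
  # H on N: anti to the previous residue's C=O, 1.0 A bond length
  prev <- match(paste(res$chain_id, res$residue_number - 1),
                paste(res$chain_id, res$residue_number))
  hvec <- cbind(res$cx[prev] - res$ox[prev],
                res$cy[prev] - res$oy[prev],
                res$cz[prev] - res$oz[prev])
  hlen <- sqrt(rowSums(hvec^2))
  hx <- res$nx + hvec[, 1] / hlen
  hy <- res$ny + hvec[, 2] / hlen
  hz <- res$nz + hvec[, 3] / hlen
  can_donate <- !is.na(prev) & canonical_aa(res$residue_name) != "PRO"
  don <- which(can_donate)
  if (!length(don)) return(tibble())
  pairs <- purrr::map(don, function(i) {
    d2 <- (res$cax - res$cax[i])^2 + (res$cay - res$cay[i])^2 +
          (res$caz - res$caz[i])^2
    j <- which(d2 < max_ca_dist^2)
    j <- j[j != i & j != prev[i]]
    if (!length(j)) return(NULL)
    r_on <- sqrt((res$ox[j] - res$nx[i])^2 + (res$oy[j] - res$ny[i])^2 +
                 (res$oz[j] - res$nz[i])^2)
    r_ch <- sqrt((res$cx[j] - hx[i])^2 + (res$cy[j] - hy[i])^2 +
                 (res$cz[j] - hz[i])^2)
    r_oh <- sqrt((res$ox[j] - hx[i])^2 + (res$oy[j] - hy[i])^2 +
                 (res$oz[j] - hz[i])^2)
    r_cn <- sqrt((res$cx[j] - res$nx[i])^2 + (res$cy[j] - res$ny[i])^2 +
                 (res$cz[j] - res$nz[i])^2)
    e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    keep <- e < e_cut
    if (!any(keep)) return(NULL)
    j <- j[keep]
    tibble(chain_id = res$chain_id[i],
           residue_number = res$residue_number[i],
           chain_id_acc = res$chain_id[j],
           residue_number_acc = res$residue_number[j],
           energy = e[keep],
           sep = ifelse(res$chain_id[j] == res$chain_id[i],
                        res$residue_number[i] - res$residue_number[j],
                        NA_integer_))
  })
  bind_rows(pairs)
}

#' Secondary structure from the hydrogen-bond pattern
#'
#' Minimal DSSP-like mapping onto \{helix, sheet, other\}: residues covered
#' by i -> i+3/i+4/i+5 turn hydrogen bonds are helix; residues donating or
#' accepting a long-range (|sep| >= 5 or inter-chain) backbone bond and not
#' helix are sheet.
#'
#' @param s A `pore_structure`.
#' @return Tibble `chain_id`, `residue_number`, `secondary`.
#' @export
secondary_structure <- function(s) {
  res <- s[s$is_protein & s$atom_name == "CA",
           c("chain_id", "residue_number")]
  res <- distinct(res)
  res$secondary <- "other"
  hb <- backbone_hbonds(s)
  if (nrow(hb) == 0) return(res)
  turns <- hb[!is.na(hb$sep) & hb$sep %in% 3:5, , drop = FALSE]
  if (nrow(turns)) {
    covered <- purrr::pmap(list(turns$chain_id, turns$residue_number_acc,
                                turns$sep),
                           function(ch, acc, k)
                             tibble(chain_id = ch,
                                    residue_number = seq(acc, acc + k)))
    covered <- distinct(bind_rows(covered))
    res$secondary[paste(res$chain_id, res$residue_number) %in%
                    paste(covered$chain_id, covered$residue_number)] <- "helix"
  }
  longr <- hb[is.na(hb$sep) | abs(hb$sep) >= 5, , drop = FALSE]
  if (nrow(longr)) {
    inb <- paste(res$chain_id, res$residue_number) %in%
      c(paste(longr$chain_id, longr$residue_number),
        paste(longr$chain_id_acc, longr$residue_number_acc))
    res$secondary[inb & res$secondary != "helix"] <- "sheet"
  }
  res
}

#' Detect a pi-bulge in a pore-lining helix
#'
#' A pi-helical segment is called when at least `min_run` consecutive
#' residues accept an i -> i+5 backbone hydrogen bond (DSSP energy below
#' the cutoff). Reported is the residue interval covered by those bonds,
#' together with i -> i+4 and i -> i+5 bond counts over the span.
#'
#' @param s A `pore_structure`.
#' @param helix_residues Residue span (2-vector or explicit numbers).
#' @param chain Optional chain; default: call per chain and report the
#'   consensus (bulge if found in any chain, interval from the first).
#' @param min_run Minimum number of consecutive i -> i+5 acceptors
#'   (default 2).
#' @param e_cut Hydrogen-bond energy cutoff.
#' @return A `helix_conformation` list: `conformation` ("pi_bulge" or
#'   "alpha"), `bulge` (residue interval or `NULL`), `n_alpha_bonds`,
#'   `n_pi_bonds`, `per_chain` detail tibble.
#' @export
detect_pi_bulge <- function(s, helix_residues, chain = NULL, min_run = 2,
                            e_cut = -0.5) {
  if (length(helix_residues) == 2) helix_residues <-
      seq(helix_residues[1], helix_residues[2])
  sel <- residue_atoms(s, helix_residues, chain = chain)
  if (nrow(sel) == 0) abort("helix selection resolves to no atoms")
  if (!all(c("N", "CA", "C", "O") %in% sel$atom_name))
    abort("missing backbone atoms in helix selection")
  hb <- backbone_hbonds(sel, e_cut = e_cut)
  chains <- unique(sel$chain_id)
  per_chain <- purrr::map(chains, function(ch) {
    h <- hb[hb$chain_id == ch & !is.na(hb$sep), , drop = FALSE]
    acc5 <- sort(unique(h$residue_number_acc[h$sep == 5]))
    runs <- if (length(acc5)) split(acc5, cumsum(c(1, diff(acc5) != 1)))
            else list()
    runs <- runs[purrr::map_int(runs, length) >= min_run]
    bulge <- if (length(runs)) {
      r <- runs[[which.max(purrr::map_int(runs, length))]]
      c(min(r), max(r) + 5)      # span covered by the i -> i+5 bonds
    } else NULL
    tibble(chain_id = ch,
           n_alpha_bonds = sum(h$sep == 4),
           n_pi_bonds = sum(h$sep == 5),
           bulge_start = if (is.null(bulge)) NA_integer_ else bulge[1],
           bulge_end = if (is.null(bulge)) NA_integer_ else bulge[2])
  }) |> bind_rows()
  has <- !is.na(per_chain$bulge_start)
  out <- list(conformation = if (any(has)) "pi_bulge" else "alpha",
              bulge = if (any(has))
                c(min(per_chain$bulge_start[has]),
                  max(per_chain$bulge_end[has])) else NULL,
              n_alpha_bonds = sum(per_chain$n_alpha_bonds),
              n_pi_bonds = sum(per_chain$n_pi_bonds),
              per_chain = per_chain)
  class(out) <- "helix_conformation"
  out
}

#' @export
print.helix_conformation <- function(x, ...) {
  cat("<helix_conformation>", x$conformation)
  if (!is.null(x$bulge))
    cat(" [residues ", x$bulge[1], "-", x$bulge[2], "]", sep = "")
  cat("  (", x$n_alpha_bonds, " alpha / ", x$n_pi_bonds, " pi bonds)\n",
      sep = "")
  invisible(x)
}

#' Assemble the per-criterion evidence record for state calling
#'
#' @param s6_conformation `"alpha"` or `"pi_bulge"`.
#' @param r_gate Minimal gate radius (Angstrom).
#' @param hydrated,conducting `TRUE`, `FALSE` or `NA` (unknown; static-only
#'   input).
#' @param gate_mhp Optional mean total MHP over the gate surface.
#' @param packing Optional mean 3D-1D score over the gate residues.
#' @param contact_complementarity Optional label
#'   (`"hydrophobic-hydrophobic"`, `"hydrophilic-hydrophobic"`, ...).
#' @export
state_evidence <- function(s6_conformation, r_gate, hydrated = NA,
                           conducting = NA, gate_mhp = NA_real_,
                           packing = NA_real_,
                           contact_complementarity = NA_character_) {
  stopifnot(s6_conformation %in% c("alpha", "pi_bulge"))
  list(s6_conformation = s6_conformation, r_gate = r_gate,
       hydrated = hydrated, conducting = conducting, gate_mhp = gate_mhp,
       packing = packing,
       contact_complementarity = contact_complementarity)
}

#' Call the pore state from the evidence record
#'
#' Deterministic rule table over the five criteria (S6 conformation, gate
#' radius, hydration/conduction, gate hydrophobicity, packing/contacts):
#' alpha-helical S6 gives `alpha_closed` (or `intermediate` when the gate
#' is wide, the transitional "alpha-open" geometry); a pi-bulge with a wide
#' (>= `wide`) hydrated/conducting gate gives `pi_open`; a pi-bulge with a
#' narrow (<= `narrow`) or dry gate gives `pi_closed`; anything else is
#' `intermediate`. With unknown dynamics the call falls back on geometry
#' alone and is flagged low-confidence.
#'
#' @param evidence A [state_evidence()] record.
#' @param wide,narrow Gate-radius thresholds (Angstrom), bracketing the
#'   open (~2.8-2.9) versus closed (~0.5-1.3) gate radii of TRPV
#'   structures; heuristic, documented as such.
#' @return A `state_call`: list with `label`, `confidence`, `evidence`.
#' @export
call_state <- function(evidence, wide = 2.0, narrow = 1.5) {
  e <- evidence
  if (is.null(e$s6_conformation) || is.null(e$r_gate) ||
      is.na(e$r_gate))
    abort("evidence record incomplete: need s6_conformation and r_gate")
  dyn_known <- !is.na(e$hydrated) || !is.na(e$conducting)
  lab <- if (e$s6_conformation == "alpha") {
    if (e$r_gate >= wide) "intermediate" else "alpha_closed"
  } else {
    open_dyn <- isTRUE(e$hydrated) || isTRUE(e$conducting)
    closed_dyn <- isFALSE(e$hydrated) && isFALSE(e$conducting)
    if (e$r_gate >= wide) {
      if (open_dyn || !dyn_known) "pi_open"
      else "intermediate"               # wide but demonstrably dry
    } else if (e$r_gate <= narrow) {
      if (open_dyn) "intermediate"      # narrow yet conducting: conflict
      else "pi_closed"
    } else {
      if (closed_dyn) "pi_closed" else "intermediate"
    }
  }
  structure(list(label = lab,
                 confidence = if (dyn_known) "full" else "static-only",
                 evidence = e),
            class = "state_call")
}

#' @export
print.state_call <- function(x, ...) {
  cat("<state_call>", x$label, paste0("(", x$confidence, ")"), "\n")
  invisible(x)
}

#' One-stop static classification of a pore structure
#'
#' Runs pi-bulge detection, the radius profile and the gate minimum with a
#' channel configuration, then calls the state (dynamic evidence stays
#' unknown for static input).
#'
#' @param s A typed `pore_structure`.
#' @param config A [channel_config()] list.
#' @param hydrated,conducting Optional trajectory-derived flags.
#' @param z_step Radius-profile step.
#' @return A `state_call` with the radius profile attached as attribute.
#' @export
classify_structure <- function(s, config, hydrated = NA, conducting = NA,
                               z_step = 0.25) {
  axis <- build_pore_axis(s, config$axis_residues)
  prof <- radius_profile(s, axis, z_step = z_step)
  gz <- gate_region_z(s, seq(config$gate_region_residues[1],
                             config$gate_region_residues[2]))
  rg <- gate_radius(prof, gz)
  conf <- detect_pi_bulge(s, config$s6_range)
  ev <- state_evidence(conf$conformation, as.numeric(rg),
                       hydrated = hydrated, conducting = conducting)
  out <- call_state(ev)
  attr(out, "radius_profile") <- prof
  attr(out, "helix_conformation") <- conf
  out
}
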