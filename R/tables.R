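#' Shipped parameter tables
#'
#' Versioned plain-text data shipped with the package: element-based van der
#' Waals radii (Bondi set), united-atom Wildman-Crippen atomic logP
#' contributions per protein heavy atom, the residue-environment class
#' thresholds, the (synthetic, surrogate) 3D-1D environment score table, the
#' per-channel pore definitions for TRPV1/3/6 and the cross-channel S6
#' alignment used for score-profile correlations.
#'
#' @return A tibble (or list for [channel_config()]).
#' @name shipped-tables
NULL

#' @rdname shipped-tables
#' @export
vdw_radius_table <- function() pm_table("vdw_radii_bondi_v1.csv")

#' @rdname shipped-tables
#' @export
hydrophobicity_table <- function() pm_table("wildman_crippen_protein_v1.csv")

#' @rdname shipped-tables
#' @export
score_table <- function() {
  tab <- pm_table("score3d1d_synthetic_v1.csv")
  attr(tab, "score_table_id") <- "synthetic-v1"
  tab
}

#' Residue-environment class thresholds
#'
#' Classes follow the 3D-1D profile convention: side-chain buried area
#' (\eqn{\ge} 114 A^2 buried B, 40-114 partial P, < 40 exposed E) subdivided
#' by the polar fraction of the buried surface (B1 < 0.45, B2 0.45-0.58,
#' B3 > 0.58; P1 < 0.67, P2 >= 0.67), crossed with secondary structure
#' (helix / sheet / other) for 18 classes in total.
#'
#' @return Named list with `buried_lo`, `buried_hi`, and the polar-fraction
#'   breakpoints for the B and P classes.
#' @export
environment_thresholds <- function() {
  list(buried_lo = 40, buried_hi = 114,
       b_breaks = c(0.45, 0.58), p_break = 0.67)
}

#' @rdname shipped-tables
#' @param channel Channel key: `"trpv1"`, `"trpv3"` or `"trpv6"`.
#' @export
channel_config <- function(channel = c("trpv1", "trpv3", "trpv6")) {
  channel <- match.arg(channel)
  if (is.null(.pm_env$channels)) {
    .pm_env$channels <- jsonlite::fromJSON(pm_extdata("channels_trpv.json"),
                                           simplifyVector = TRUE)
  }
  cfg <- .pm_env$channels[[channel]]
  cfg$channel <- channel
  cfg
}

#' @rdname shipped-tables
#' @export
s6_alignment <- function() pm_table("s6_alignment_trpv.csv")
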