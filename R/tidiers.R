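#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy/glance methods for fitted result objects
#'
#' `tidy()` returns the per-element detail of a result as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Ignored.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.state_call <- function(x, ...) {
  e <- x$evidence
  tibble(criterion = c("s6_conformation", "r_gate", "hydrated", "conducting",
                       "gate_mhp", "packing", "contact_complementarity"),
         value = c(e$s6_conformation, format(e$r_gate), e$hydrated,
                   e$conducting, format(e$gate_mhp), format(e$packing),
                   e$contact_complementarity))
}

#' @rdname tidiers
#' @export
glance.state_call <- function(x, ...) {
  tibble(label = x$label, confidence = x$confidence,
         r_gate = x$evidence$r_gate,
         s6_conformation = x$evidence$s6_conformation)
}

#' @rdname tidiers
#' @export
tidy.helix_conformation <- function(x, ...) x$per_chain

#' @rdname tidiers
#' @export
glance.helix_conformation <- function(x, ...) {
  tibble(conformation = x$conformation,
         bulge_start = if (is.null(x$bulge)) NA_integer_ else x$bulge[1],
         bulge_end = if (is.null(x$bulge)) NA_integer_ else x$bulge[2],
         n_alpha_bonds = x$n_alpha_bonds, n_pi_bonds = x$n_pi_bonds)
}

#' @rdname tidiers
#' @export
tidy.esa_profile <- function(x, ...) x$profile

#' @rdname tidiers
#' @export
glance.esa_profile <- function(x, ...) {
  tibble(esa_total = x$esa_total, esa_hydrophobic = x$esa_hydrophobic,
         region_lo = x$region[1], region_hi = x$region[2],
         n_frames = x$n_frames)
}

#' @rdname tidiers
#' @export
glance.radius_profile <- function(x, ...) {
  i <- which.min(x$radius)
  tibble(r_min = x$radius[i], z_min = x$z[i], n_capped = sum(x$capped))
}

#' @rdname tidiers
#' @export
tidy.density_field <- function(x, ...) x$axial

#' @rdname tidiers
#' @export
glance.density_field <- function(x, ...) {
  tibble(species = x$species, n_frames = x$n_frames,
         mean_count_in_cylinder = sum(x$axial$count))
}
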