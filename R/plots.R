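#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_tile
#'   scale_fill_gradient2 labs theme_minimal geom_text facet_wrap
NULL

#' Plot a cylindrical projection map
#'
#' @param object A `cyl_map`.
#' @param value Column to colour by (default `"total"` for MHP maps,
#'   `"score"` otherwise).
#' @param ... Ignored.
#' @return A ggplot: angle on x, z on y, property as fill, diverging scale
#'   centred at 0 (brown hydrophobic, blue hydrophilic by convention).
#' @export
autoplot.cyl_map <- function(object, value = NULL, ...) {
  value <- value %||%
    (if (identical(attr(object, "property"), "mhp")) "total" else "score")
  ggplot(object[object$hit, ], aes(.data$angle, .data$z,
                                   fill = .data[[value]])) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f4",
                         high = "#8c510a", midpoint = 0) +
    labs(x = "rotation angle (deg)", y = "z (Å)",
         fill = paste0(value, "\n(logP)")) +
    theme_minimal()
}

#' @rdname autoplot.cyl_map
#' @export
plot_map <- function(object, value = NULL, ...) autoplot.cyl_map(object, value, ...)

#' Plot a pore-radius profile
#' @param object A `radius_profile`.
#' @param ... Ignored.
#' @export
autoplot.radius_profile <- function(object, ...) {
  ggplot(object, aes(.data$z, .data$radius)) +
    geom_line() +
    labs(x = "z (Å)", y = "pore radius (Å)") +
    theme_minimal()
}

#' Plot self/induced/total MHP profiles along the pore axis
#' @param object An `axial_profile`.
#' @param ... Ignored.
#' @export
autoplot.axial_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("z", "self", "induced",
                                                    "total")],
                              -"z", names_to = "component",
                              values_to = "mhp")
  ggplot(long, aes(.data$z, .data$mhp, colour = .data$component)) +
    geom_line() +
    labs(x = "z (Å)", y = "MHP (logP units)") +
    theme_minimal()
}

#' Plot an ESA profile and its MHP histogram
#' @param object An `esa_profile`.
#' @param which `"profile"` or `"histogram"`.
#' @param ... Ignored.
#' @export
autoplot.esa_profile <- function(object, which = c("profile", "histogram"),
                                 ...) {
  which <- match.arg(which)
  if (which == "profile") {
    long <- tidyr::pivot_longer(object$profile, -"z", names_to = "kind",
                                values_to = "area")
    ggplot(long, aes(.data$z, .data$area, colour = .data$kind)) +
      geom_line() +
      labs(x = "z (Å)", y = "exposed area (Å²)") +
      theme_minimal()
  } else {
    ggplot(object$histogram, aes(.data$mhp, .data$area)) +
      geom_line() +
      labs(x = "MHP (logP units)", y = "exposed area (Å²)") +
      theme_minimal()
  }
}

#' Heatmap of a score-profile correlation matrix
#' @param m Symmetric correlation matrix from [correlation_matrix()].
#' @export
plot_correlation_matrix <- function(m) {
  df <- as_tibble(as.data.frame(as.table(m)))
  names(df) <- c("a", "b", "r")
  ggplot(df, aes(.data$a, .data$b, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0, limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "R") +
    theme_minimal()
}
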