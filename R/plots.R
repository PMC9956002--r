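#' Heatmap of site-by-substrate interaction times
#'
#' @param object A `binding_sites` tibble.
#' @param ... Unused.
#' @return A ggplot: tiles of interaction time (ns) per site and
#'   substrate, sites ordered by id from the top.
#' @export
autoplot.binding_sites <- function(object, ...) {
  long <- site_times_long(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$substrate,
                               y = factor(.data$site_id,
                                          levels = rev(sort(unique(.data$site_id)))),
                               fill = .data$time_ns)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$time_ns)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 name = "time [ns]") +
    ggplot2::labs(x = "substrate", y = "transient binding site") +
    ggplot2::theme_minimal()
}

#' Stability-versus-character view of a mutant library
#'
#' @param object A `mutant_library` tibble.
#' @param ... Unused.
#' @return A ggplot of ddG against the physicochemical-change score, one
#'   labelled point per proposed mutant.
#' @export
autoplot.mutant_library <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$physchem_score),
                               y = .data$ddg_kcal_mol)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$mutation),
                       hjust = -0.2, size = 3) +
    ggplot2::labs(x = "physicochemical-change score",
                  y = expression(Delta * Delta * G ~ "[kcal/mol]")) +
    ggplot2::theme_minimal()
}

#' Contact-map raster for one replica
#'
#' @param m A [contact_matrix()].
#' @return A ggplot raster of the sparse residue-by-frame contact entries.
#' @export
plot_contact_map <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  ggplot2::ggplot(as_tibble(m),
                  ggplot2::aes(x = .data$frame, y = .data$residue)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "frame", y = "residue",
                  title = sprintf("%s / %s", attr(m, "substrate"),
                                  attr(m, "replica"))) +
    ggplot2::theme_minimal()
}
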