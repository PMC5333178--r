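# Broom-style accessors and plots for simplification results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simplification result
#'
#' For the automatic scheme, the per-iteration trace (iteration, complex
#' interval count and size, points newly marked simple, total complexity and
#' improvement); for an interactive result, the state intervals.
#'
#' @param x A `ligand_simplification`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ligand_simplification <- function(x, ...) {
  if (!is.null(x$trace)) x$trace else x$state
}

#' One-row summary of a simplification result
#'
#' @param x A `ligand_simplification`.
#' @param ... Unused.
#' @return A one-row tibble with the back end, iteration count, initial and
#'   final total complexity, point counts and convergence flags.
#' @export
glance.ligand_simplification <- function(x, ...) {
  tibble(
    backend = x$backend,
    n_points = nrow(x$trajectory),
    n_intervals = nrow(x$state),
    max_level = max(x$state$level),
    iterations = if (!is.null(x$trace)) max(x$trace$iteration) else NA_integer_,
    initial_complexity = x$initial_complexity,
    final_complexity = x$final_complexity,
    converged = x$converged,
    hit_cap = x$hit_cap
  )
}

#' @export
autoplot.ligand_simplification <- function(object, ...) {
  if (!is.null(object$trace)) {
    ggplot2::ggplot(object$trace,
                    ggplot2::aes(x = .data$iteration, y = .data$total_complexity)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "iteration", y = "total complexity",
                    title = "Automatic simplification convergence") +
      ggplot2::theme_minimal()
  } else {
    st <- object$state
    ggplot2::ggplot(st, ggplot2::aes(xmin = start, xmax = end,
                                     ymin = 0, ymax = level)) +
      ggplot2::geom_rect(fill = "#3465a4", alpha = 0.7) +
      ggplot2::labs(x = "time step", y = "simplification level") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.attribute_table <- function(object, ...) {
  keep <- intersect(c("dist_active_site", "stuckness", "speed", "free_space",
                      "hydrophobicity"), names(object))
  long <- tidyr::pivot_longer(object[, c("step", keep)], -step,
                              names_to = "attribute", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = step, y = value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#204a87") +
    ggplot2::facet_wrap(~attribute, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time step", y = NULL,
                  title = "Ligand trajectory attributes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ligand_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = x, y = z, colour = step)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Ligand trajectory (",
                                 attr(object, "provenance") %||% "raw", ")"),
                  x = "x [Å]", y = "z [Å]") +
    ggplot2::theme_minimal()
}
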