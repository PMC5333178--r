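# Static exports of the exploration views: the 1D category overview, the
# lining-residue timelines, and raw + smoothed scatter data. All correctness
# lives in the CSV/tibble exports; the PNG renderings are best-effort.

#' Trajectory overview track
#'
#' The per-step positional category as a 1D colour track (outside white,
#' surface blue, inside orange, active site red).
#'
#' @param table An attribute table from [derive_attributes()] (or any data
#'   frame with `step` and `category` columns).
#' @param csv,png Optional output paths.
#' @return A tibble of class `overview_track` with columns `step`,
#'   `category`.
#' @export
build_overview <- function(table, csv = NULL, png = NULL) {
  if (!all(c("step", "category") %in% names(table)))
    abort("the table needs step and category columns")
  if (nrow(table) == 0) abort("the table is empty")
  track <- structure(tibble(step = table$step, category = table$category),
                     class = c("overview_track", class(tibble())))
  if (!is.null(csv)) readr::write_csv(track, csv)
  if (!is.null(png)) save_plot(autoplot(track), png, height = 1.6)
  track
}

#' @export
autoplot.overview_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = step, y = 1, fill = category)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_manual(values = category_colors(), drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time step", y = NULL, fill = NULL,
                  title = "Ligand position overview") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Run-length encoding of an overview track
#'
#' Contiguous category blocks with half-open step ranges, for comparison
#' with a known phase plan.
#'
#' @param track An `overview_track` (or `step`/`category` data frame).
#' @return A tibble with columns `category`, `start`, `end`.
#' @export
overview_runs <- function(track) {
  r <- rle(track$category)
  ends <- cumsum(r$lengths)
  tibble(category = r$values,
         start = track$step[c(1, head(ends, -1) + 1)],
         end = track$step[ends] + 1L)
}

#' Lining-residue timelines
#'
#' One line per residue: the half-open step intervals in which the residue
#' is among the k closest to the ligand, coloured by a physico-chemical
#' property. Interruptions appear exactly where the residue drops out of the
#' lining set.
#'
#' @param lining Long lining table (`step`, `residue`, `resname`), e.g.
#'   [lining_table()] of an attribute table.
#' @param property `"hydrophobicity"`, `"charge"` or `"donor_acceptor"`.
#' @param scale Hydrophobicity scale used when `property` is
#'   `"hydrophobicity"`.
#' @param csv,png Optional output paths.
#' @return A tibble of class `residue_timeline` with columns `residue`,
#'   `resname`, `start`, `end` (half-open step ranges) and `value`.
#' @export
build_residue_timelines <- function(lining,
                                    property = c("hydrophobicity", "charge",
                                                 "donor_acceptor"),
                                    scale = kyte_doolittle(),
                                    csv = NULL, png = NULL) {
  property <- tryCatch(match.arg(property),
                       error = function(e) abort(paste0(
                         "unknown property; use hydrophobicity, charge or donor_acceptor")))
  if (!all(c("step", "residue", "resname") %in% names(lining)))
    abort("lining table needs step, residue and resname columns")

  timeline <- lining |>
    arrange(.data$residue, step) |>
    group_by(.data$residue, .data$resname) |>
    summarise(intervals = list(presence_intervals(step)), .groups = "drop") |>
    tidyr::unnest("intervals")

  timeline$value <- switch(
    property,
    hydrophobicity = unname(scale[toupper(timeline$resname)]),
    charge = residue_formal_charge(timeline$resname),
    donor_acceptor = donor_acceptor_class(timeline$resname)
  )
  timeline <- structure(as_tibble(timeline), property = property,
                        class = c("residue_timeline", class(tibble())))
  if (!is.null(csv)) readr::write_csv(timeline, csv)
  if (!is.null(png)) save_plot(autoplot(timeline), png,
                               height = max(2, 0.18 * length(unique(timeline$residue))))
  timeline
}

# half-open intervals of consecutive steps
presence_intervals <- function(steps) {
  steps <- sort(unique(steps))
  run_id <- cumsum(c(1L, diff(steps) != 1L))
  tibble(start = as.integer(tapply(steps, run_id, min)),
         end = as.integer(tapply(steps, run_id, max)) + 1L)
}

#' Expand a residue timeline back to per-step lining sets
#'
#' The inverse of [build_residue_timelines()]: useful to verify that the
#' intervals reconstruct the lining table losslessly.
#'
#' @param timeline A `residue_timeline`.
#' @return A tibble with columns `step`, `residue`.
#' @export
timeline_to_steps <- function(timeline) {
  purrr::pmap_dfr(timeline[, c("residue", "start", "end")],
                  function(residue, start, end)
                    tibble(step = start:(end - 1L), residue = residue)) |>
    arrange(step, .data$residue)
}

#' @export
autoplot.residue_timeline <- function(object, ...) {
  property <- attr(object, "property") %||% "value"
  ord <- object |> group_by(.data$residue) |> summarise(first = min(start))
  object$residue <- factor(object$residue,
                           levels = ord$residue[order(ord$first)])
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(xmin = start, xmax = end,
                                    ymin = as.integer(.data$residue) - 0.4,
                                    ymax = as.integer(.data$residue) + 0.4,
                                    fill = .data$value)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(object$residue)),
                                labels = levels(object$residue)) +
    ggplot2::labs(x = "time step", y = NULL, fill = property,
                  title = "Ligand-lining residues") +
    ggplot2::theme_minimal()
  if (is.numeric(object$value))
    p <- p + ggplot2::scale_fill_gradient2(low = "#3465a4", mid = "grey90",
                                           high = "#f57900", midpoint = 0)
  p
}

#' Export raw and smoothed scatter data for two attributes
#'
#' Emits the raw and sliding-window-smoothed series of a pair of attributes
#' (the data behind one scatterplot-matrix panel) and, optionally, a static
#' scatter image of each.
#'
#' @param table An attribute table.
#' @param x_attr,y_attr Column names in `table`.
#' @param window Odd sliding-window size (default 9); 1 disables smoothing.
#' @param csv,png Optional output paths.
#' @return A tibble with columns `step`, `x_raw`, `y_raw`, `x_smooth`,
#'   `y_smooth`; attributes `x_attr`/`y_attr`.
#' @export
export_scatter_data <- function(table, x_attr, y_attr, window = 9,
                                csv = NULL, png = NULL) {
  for (a in c(x_attr, y_attr)) {
    if (!a %in% names(table))
      abort(paste0("attribute '", a, "' not in table; available: ",
                   paste(names(table), collapse = ", ")))
    if (!is.numeric(table[[a]]))
      abort(paste0("attribute '", a, "' is not numeric"))
  }
  out <- tibble(
    step = table$step,
    x_raw = table[[x_attr]], y_raw = table[[y_attr]],
    x_smooth = sliding_window(table[[x_attr]], window),
    y_smooth = sliding_window(table[[y_attr]], window)
  )
  out <- structure(out, x_attr = x_attr, y_attr = y_attr,
                   class = c("scatter_export", class(tibble())))
  if (!is.null(csv)) readr::write_csv(out, csv)
  if (!is.null(png)) save_plot(autoplot(out), png)
  out
}

#' @export
autoplot.scatter_export <- function(object, ...) {
  long <- bind_rows(
    tibble(x = object$x_raw, y = object$y_raw, series = "raw"),
    tibble(x = object$x_smooth, y = object$y_smooth, series = "smoothed")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "#3465a4") +
    ggplot2::facet_wrap(~series, ncol = 1) +
    ggplot2::labs(x = attr(object, "x_attr"), y = attr(object, "y_attr")) +
    ggplot2::theme_minimal()
}

save_plot <- function(p, path, width = 8, height = 4) {
  suppressMessages(ggplot2::ggsave(path, plot = p, width = width,
                                   height = height, dpi = 120))
  invisible(path)
}
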