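#' Plot the projected conformational space
#'
#' Scatter of the shared 2-D embedding, optionally colored by a per-point
#' observable track (e.g. radius of gyration) or faceted by model.
#'
#' @param object a `conf_projection`.
#' @param track optional numeric vector or [observable_track()] tibble used as
#'   the color scale.
#' @param facet_by_model draw one panel per model, others in grey.
#' @param point_size passed to `geom_point()`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.conf_projection <- function(object, track = NULL, facet_by_model = FALSE,
                                     point_size = 0.8, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(track)) {
    df$value <- if (is.data.frame(track)) track$value else as.numeric(track)
    name <- if (is.data.frame(track)) attr(track, "observable") %||% "value" else "value"
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$value)) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::scale_colour_viridis_c(name = name)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::scale_colour_brewer(palette = "Dark2", name = "model")
  }
  if (facet_by_model) {
    bg <- dplyr::select(df, -"label")
    p <- p + ggplot2::geom_point(data = bg, colour = "grey80", size = point_size) +
      ggplot2::geom_point(size = point_size) +
      ggplot2::facet_wrap(~label)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "projection 1", y = "projection 2")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a relative-fraction surface
#'
#' Heat map of one model's per-bin occupancy proportion over the projection
#' grid; bins at fraction 1 are exclusively populated by the model.
#'
#' @param occ a [bin_projection()] result.
#' @param model model label.
#' @return A ggplot object.
#' @export
plot_fraction_map <- function(occ, model) {
  df <- relative_fraction_map(occ, model)
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$fraction)),
                  ggplot2::aes(.data$x, .data$y, fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1),
                                  name = sprintf("F (%s)", model)) +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "projection 1", y = "projection 2")
}

#' Plot the density-overlap matrix
#'
#' @param object an `overlap_table` from [overlap_matrix()] or
#'   [overlap_uncertainty()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.overlap_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$w, .data$z, fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$overlap)), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "overlap") +
    ggplot2::theme_minimal() + ggplot2::labs(x = NULL, y = NULL)
}

#' Plot normalised projection entropies with replicate spread
#'
#' @param object an `entropy_report` from [entropy_across_replicates()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.entropy_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$label, .data$mean_normalized)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_normalized - .data$sd_normalized,
      ymax = .data$mean_normalized + .data$sd_normalized)) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal() +
    ggplot2::labs(x = "model", y = "normalised projection entropy")
}

#' Plot the projection stratified by binding sector
#'
#' @param proj a `conf_projection`.
#' @param trace a `sector_trace` aligned with `proj` (see
#'   [stratify_projection()]).
#' @param point_size passed to `geom_point()`.
#' @return A ggplot object.
#' @export
plot_sector_overlay <- function(proj, trace, point_size = 0.8) {
  df <- stratify_projection(proj, trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = factor(.data$sector))) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_brewer(palette = "Set1", name = "sector") +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "projection 1", y = "projection 2")
}

#' Plot a contact-frequency map
#'
#' @param cmap matrix from [contact_map()] (or an [extract_lcs()] result).
#' @return A ggplot object.
#' @export
plot_contact_map <- function(cmap) {
  if (inherits(cmap, "lcs_result")) cmap <- cmap$contact_map
  df <- tibble::tibble(
    i = rep(seq_len(nrow(cmap)), times = ncol(cmap)),
    j = rep(seq_len(ncol(cmap)), each = nrow(cmap)),
    frequency = as.vector(cmap)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "residue i", y = "residue j")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
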