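#' Plot an RMSD time series
#'
#' @param object An `rmsd_series` tibble (rows from several domains/systems
#'   may be combined with [dplyr::bind_rows()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsd_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$time_ps / 1000, .data$rmsd_A, colour = .data$domain
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)", colour = "domain") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' @param object An `rmsf_profile`.
#' @param map Optional `domain_map` used to colour residues by domain.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsf_profile <- function(object, map = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(map)) {
    d$domain <- assign_residue_domain(map, d$chain, d$residue_id)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$residue_id, .data$rmsf_A)) +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
  if (is.null(map)) {
    p + ggplot2::geom_line()
  } else {
    p + ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey70") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$domain), size = 0.8)
  }
}

#' Box plot of domain-assigned RMSF values
#'
#' Draws the precomputed Tukey statistics (hinge quartiles, 1.5 IQR
#' whiskers, outlier points) per domain.
#'
#' @param stats A `domain_box_stats` tibble.
#' @return A ggplot.
#' @export
plot_domain_rmsf <- function(stats) {
  outl <- tidyr::unnest(
    tibble::as_tibble(stats)[, c("domain", "outliers")], "outliers"
  )
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$domain)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity", width = 0.6
    ) +
    ggplot2::geom_point(data = outl, ggplot2::aes(y = .data$rmsf_A),
                        shape = 1) +
    ggplot2::labs(x = "domain", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Heat-map of a time-averaged RMSD matrix
#'
#' @param object An `rmsd_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsd_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$co, .data$focal,
                                       fill = .data$mean_rmsd_A)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_rmsd_A)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(name = "mean RMSD (Å)") +
    ggplot2::labs(x = "co-compound", y = "focal compound") +
    ggplot2::theme_minimal()
}

#' Tile plot of a domain contact competition matrix
#'
#' Off-diagonal tiles are coloured by the direction of change relative to
#' the focal compound's single-species value.
#'
#' @param object A `competition_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.competition_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$co, .data$focal,
                                       fill = .data$annotation)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$c_domain),
      fontface = ifelse(.data$diagonal, "bold", "plain")
    ), size = 3) +
    ggplot2::scale_fill_manual(values = c(
      diagonal = "grey85", increase = "#f4a6b8", decrease = "#a6cee3",
      unchanged = "white"
    ), na.value = "grey95") +
    ggplot2::labs(x = "co-compound", y = "focal compound",
                  title = paste("Domain", attr(object, "domain"))) +
    ggplot2::theme_minimal()
}

#' Rose plot of cell tracks from a common origin
#'
#' Each track is translated so it starts at the origin, the standard way of
#' displaying random-migration data.
#'
#' @param object A `cell_tracks` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_tracks <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("condition", "cell_id")))) |>
    dplyr::mutate(x_um = .data$x_um - .data$x_um[1],
                  y_um = .data$y_um - .data$y_um[1]) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_um, .data$y_um,
                                       group = .data$cell_id)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(d)) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' Per-residue average contact profile
#'
#' @param object A `contact_series`.
#' @param ... Unused.
#' @return A ggplot of average contact number against residue id, one facet
#'   per species.
#' @export
autoplot.contact_series <- function(object, ...) {
  ggplot2::ggplot(object$averages, ggplot2::aes(
    .data$residue_id, .data$avg_contacts
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(species ~ chain, scales = "free_x") +
    ggplot2::labs(x = "residue",
                  y = expression("average contact number" ~ group(langle, C[i], rangle))) +
    ggplot2::theme_minimal()
}
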