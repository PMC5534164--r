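#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a component clustering
#'
#' One row per tested number of clusters with its within-group sum of
#' squares and the relative decrease used by the elbow rule.
#'
#' @param x A `component_clustering`.
#' @param ... Unused.
#' @return A tibble `k`, `wss`, `rel_decrease`, `chosen`.
#' @method tidy component_clustering
#' @export
tidy.component_clustering <- function(x, ...) {
  kmax <- length(x$wss)
  rel <- c(
    ifelse(x$wss[-kmax] <= 0, 0, -diff(x$wss) / x$wss[-kmax]),
    NA_real_
  )
  tibble::tibble(
    k = seq_len(kmax), wss = x$wss, rel_decrease = rel,
    chosen = seq_len(kmax) == x$k
  )
}

#' Glance at a component clustering
#'
#' @param x A `component_clustering`.
#' @param ... Unused.
#' @return A one-row tibble: `component`, `k`, `n_variables`, `wss_at_k`.
#' @method glance component_clustering
#' @export
glance.component_clustering <- function(x, ...) {
  tibble::tibble(
    component = x$component, k = x$k,
    n_variables = length(x$variables), wss_at_k = x$wss[x$k]
  )
}

#' Tidy an ELC map (its legend)
#'
#' @param x An `elc_map`.
#' @param ... Unused.
#' @return The legend tibble: one row per category with its component
#'   cluster triple, cell count and territory share.
#' @method tidy elc_map
#' @export
tidy.elc_map <- function(x, ...) {
  x$legend
}

#' Glance at an ELC map
#'
#' @param x An `elc_map`.
#' @param ... Unused.
#' @return A one-row tibble: `n_categories`, `n_land_cells`.
#' @method glance elc_map
#' @export
glance.elc_map <- function(x, ...) {
  tibble::tibble(
    n_categories = nrow(x$legend),
    n_land_cells = sum(x$legend$n_cells)
  )
}

#' Tidy a representativeness result
#'
#' @param x A `representativeness` object.
#' @param ... Unused.
#' @return Per-category tibble of territory, accession and external record
#'   shares with `represented` and `is_gap` flags.
#' @method tidy representativeness
#' @export
tidy.representativeness <- function(x, ...) {
  dplyr::mutate(
    x$freq,
    represented = .data$category %in% x$represented,
    is_gap = .data$category %in% x$gap_categories
  )
}

#' Glance at a representativeness result
#'
#' @param x A `representativeness` object.
#' @param ... Unused.
#' @return One-row tibble with category counts and the current/improvement
#'   percentages.
#' @method glance representativeness
#' @export
glance.representativeness <- function(x, ...) {
  imp <- improvement_stats(
    x$n_categories, length(x$represented), length(x$gap_categories)
  )
  tibble::tibble(
    n_categories = x$n_categories,
    n_represented = length(x$represented),
    n_gap_categories = length(x$gap_categories),
    current_pct = imp$current_pct,
    improvement_pct = imp$improvement_pct
  )
}

#' Elbow plot of a component clustering
#'
#' Within-group sum of squares against the number of clusters, with the
#' elbow-rule choice highlighted.
#'
#' @param object A `component_clustering`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot component_clustering
#' @export
autoplot.component_clustering <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "red"), guide = "none"
    ) +
    ggplot2::labs(
      x = "number of clusters k", y = "within-group sum of squares",
      title = paste0(object$component, " component (k = ", object$k, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Map plot of an ELC map
#'
#' Raster tile plot of the ELC categories over the territory.
#'
#' @param object An `elc_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot elc_map
#' @export
autoplot.elc_map <- function(object, ...) {
  g <- object$geom
  cat_v <- as.vector(object$category)
  idx <- which(!is.na(cat_v))
  cc <- cell_centers(g)
  d <- tibble::tibble(
    lon = cc$lon[idx], lat = cc$lat[idx],
    category = factor(cat_v[idx])
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "ELC category") +
    ggplot2::theme_minimal()
}

#' Gap-location plot
#'
#' Scatters the ranked external records of one species over the map
#' extent, priority ecogeographical gaps highlighted.
#'
#' @param ranked Ranked externals tibble from [priority_rank()].
#' @return A ggplot.
#' @export
plot_gaps <- function(ranked) {
  ggplot2::ggplot(
    ranked,
    ggplot2::aes(.data$longitude, .data$latitude, colour = .data$is_priority_gap)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "covered", `TRUE` = "priority gap"),
      name = NULL
    ) +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
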