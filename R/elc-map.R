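#' Elbow rule for the number of clusters
#'
#' The number of categories per ecogeographical component is the smallest
#' `n` for which the relative decrease of the within-group sum of squares
#' from `n` to `n + 1` groups falls below 50%:
#' `(WSS(n) - WSS(n+1)) / WSS(n) < 0.5`. A zero `WSS(n)` counts as a
#' decrease of 0 (stop at `n`). If every consecutive decrease up to the end
#' of the sequence is at least 50%, the maximum tested `k` is chosen.
#'
#' @param wss Numeric vector of within-group sums of squares for
#'   `k = 1..k_max`, non-increasing.
#' @param cutoff Relative-decrease cutoff (default 0.5).
#' @return The chosen number of clusters.
#' @examples
#' elbow_k(c(100, 40, 25, 20)) # 60% then 37.5%: stops at k = 2
#' @export
elbow_k <- function(wss, cutoff = 0.5) {
  if (length(wss) < 2) stop("need WSS for at least two values of k", call. = FALSE)
  if (any(diff(wss) > 1e-8 * pmax(wss[-length(wss)], 1))) {
    stop("WSS must be non-increasing in k", call. = FALSE)
  }
  for (n in seq_len(length(wss) - 1)) {
    drop_ratio <- if (wss[n] <= 0) 0 else (wss[n] - wss[n + 1]) / wss[n]
    if (drop_ratio < cutoff) {
      return(n)
    }
  }
  length(wss)
}

# Hartigan-Wong K-means that muffles the benign Quick-TRANSfer convergence
# notice (common on large grids with near-duplicate rows; the best-of-
# restarts WSS is what matters here)
kmeans_quiet <- function(xs, k, nstart) {
  withCallingHandlers(
    stats::kmeans(xs, centers = k, nstart = nstart, iter.max = 100),
    warning = function(w) {
      if (grepl("Quick-TRANSfer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Cluster one ecogeographical component
#'
#' Z-standardizes the component's selected variables over all land cells of
#' the territory (the map must cover the whole study area, not only
#' occurrence sites), runs K-means for `k = 1..k_max` with `nstart`
#' restarts per `k` keeping the best solution, picks `k` by the elbow rule,
#' and labels every land cell. Constant variables are dropped with a
#' warning; the per-`k` WSS sequence is required to come out non-increasing
#' (best-of-restarts) and the run fails otherwise.
#'
#' @param stack An [eco_stack()] (use [add_latlon_layers()] first if the
#'   selection includes `LATITUDE`/`LONGITUDE`).
#' @param component `"bioclimatic"`, `"edaphic"` or `"geophysic"`.
#' @param variables Layers to use; default all layers of the component.
#' @param k_max Maximum clusters allowed for the component.
#' @param seed Integer seed.
#' @param nstart K-means restarts per `k`.
#' @return A `component_clustering` object: fields `component`,
#'   `variables`, `scale_center`/`scale_sd`, `wss` (per k), `k`, `centers`
#'   (standardized space), `labels` (integer matrix, `NA` off-land).
#' @export
cluster_component <- function(stack, component, variables = NULL, k_max = 8,
                              seed = 1L, nstart = 10) {
  variables <- variables %||%
    names(stack$component)[stack$component == component]
  missing_l <- setdiff(variables, names(stack$layers))
  if (length(missing_l)) {
    stop("layers not in stack: ", paste(missing_l, collapse = ", "), call. = FALSE)
  }
  land <- land_mask(stack)
  x <- vapply(variables, function(v) as.vector(stack$layers[[v]])[land],
    numeric(sum(land))
  )
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste(
      "dropping constant variable(s):",
      paste(variables[sds == 0], collapse = ", ")
    ))
    variables <- variables[sds > 0]
    if (!length(variables)) {
      stop("no non-constant variables left for component ", component, call. = FALSE)
    }
    x <- x[, sds > 0, drop = FALSE]
    ctr <- ctr[sds > 0]
    sds <- sds[sds > 0]
  }
  if (sum(land) < k_max) stop("fewer land cells than k_max", call. = FALSE)
  xs <- scale(x, center = ctr, scale = sds)

  fits <- vector("list", k_max)
  wss <- numeric(k_max)
  n_distinct <- nrow(unique(xs))
  for (k in seq_len(k_max)) {
    if (k > n_distinct) {
      # fewer distinct cell profiles than centers (e.g. zero-noise zones):
      # the partition cannot improve beyond k = n_distinct
      fits[[k]] <- fits[[n_distinct]]
      wss[k] <- wss[n_distinct]
      next
    }
    set.seed(derive_seed(seed, paste0(component, "_k", k)))
    fits[[k]] <- kmeans_quiet(xs, k, nstart)
    wss[k] <- fits[[k]]$tot.withinss
    if (k > 1 && wss[k] > wss[k - 1] + 1e-8) {
      # best-of-restarts should be monotone; try harder once, then fail
      set.seed(derive_seed(seed, paste0(component, "_k", k, "_retry")))
      fits[[k]] <- kmeans_quiet(xs, k, nstart * 5)
      wss[k] <- fits[[k]]$tot.withinss
      if (wss[k] > wss[k - 1] + 1e-8) {
        stop("WSS increased from k=", k - 1, " to k=", k,
          " for component ", component,
          call. = FALSE
        )
      }
    }
  }
  k <- elbow_k(wss)
  labels <- matrix(NA_integer_, stack$nrow, stack$ncol)
  labels[land] <- fits[[k]]$cluster

  structure(
    list(
      component = component, variables = variables,
      scale_center = ctr, scale_sd = sds,
      wss = wss, k = k, centers = fits[[k]]$centers,
      labels = labels,
      geom = list(
        xmin = stack$xmin, ymin = stack$ymin,
        cell_size = stack$cell_size, nrow = stack$nrow, ncol = stack$ncol
      )
    ),
    class = "component_clustering"
  )
}

#' @export
print.component_clustering <- function(x, ...) {
  cat("<component_clustering> ", x$component, ": k = ", x$k,
    " (elbow over k_max = ", length(x$wss), "), variables: ",
    paste(x$variables, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Combine component clusterings into an ELC map
#'
#' Every land cell's ELC category is the triple of its bioclimatic, edaphic
#' and geophysic cluster labels. Observed triples are enumerated and given
#' consecutive ids 1..C in lexicographic order of (bioclimatic, edaphic,
#' geophysic); cells where any component is nodata become nodata. The
#' legend maps category id to its triple and cell count; when the stack is
#' supplied, per-category mean values of every layer are added.
#'
#' @param bio,eda,geo `component_clustering` objects on one common grid.
#' @param stack Optional [eco_stack()] for per-category variable means.
#' @return An `elc_map` object: `category` (integer matrix), `legend`
#'   (tibble `category`, `bioclimatic`, `edaphic`, `geophysic`,
#'   `n_cells`, `territory_share`, and layer means), `geom`.
#' @export
combine_components <- function(bio, eda, geo, stack = NULL) {
  dims <- list(dim(bio$labels), dim(eda$labels), dim(geo$labels))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("component grids do not match", call. = FALSE)
  }
  b <- as.vector(bio$labels)
  e <- as.vector(eda$labels)
  g <- as.vector(geo$labels)
  land <- !is.na(b) & !is.na(e) & !is.na(g)
  triple_key <- b * 100L + e * 10L + g # labels <= 8: digits cannot collide
  observed <- sort(unique(triple_key[land]))
  cat_v <- rep(NA_integer_, length(b))
  cat_v[land] <- match(triple_key[land], observed)

  legend <- tibble::tibble(
    category = seq_along(observed),
    bioclimatic = observed %/% 100L,
    edaphic = (observed %/% 10L) %% 10L,
    geophysic = observed %% 10L,
    n_cells = as.integer(table(factor(cat_v[land], levels = seq_along(observed))))
  )
  legend$territory_share <- legend$n_cells / sum(legend$n_cells)

  if (!is.null(stack)) {
    for (ly in names(stack$layers)) {
      v <- as.vector(stack$layers[[ly]])
      legend[[paste0("mean_", ly)]] <- as.vector(
        tapply(v[land], cat_v[land], mean)
      )[legend$category]
    }
  }

  cat_m <- matrix(cat_v, nrow(bio$labels), ncol(bio$labels))
  structure(
    list(category = cat_m, legend = legend, geom = bio$geom),
    class = "elc_map"
  )
}

#' @export
print.elc_map <- function(x, ...) {
  cat("<elc_map> ", nrow(x$legend), " categories over ",
    sum(x$legend$n_cells), " land cells\n",
    sep = ""
  )
  invisible(x)
}

#' Assign ELC categories to occurrence records
#'
#' Containing-cell lookup of the category raster at each record's
#' coordinates. Records in the sea margin or outside the map get category 0
#' (unassigned) with a warning and are excluded from representativeness
#' computations downstream.
#'
#' @param elc An `elc_map`.
#' @param records Occurrence tibble with `latitude`, `longitude`.
#' @return `records` with `elc_category` filled in (0 = unassigned).
#' @export
assign_category <- function(elc, records) {
  idx <- cell_index(elc$geom, records$longitude, records$latitude)
  flat <- (idx$col - 1L) * elc$geom$nrow + idx$row
  cat <- ifelse(is.na(flat), NA_integer_, elc$category[ifelse(is.na(flat), 1L, flat)])
  n_bad <- sum(is.na(cat))
  if (n_bad > 0) {
    rlang::warn(sprintf(
      "%d record(s) fall on nodata or outside the map; assigned category 0",
      n_bad
    ))
  }
  records$elc_category <- ifelse(is.na(cat), 0L, cat)
  records
}

#' Build a species' ELC map from a variable selection
#'
#' Adds latitude/longitude layers to the stack, clusters each
#' ecogeographical component on its selected variables (elbow-rule K-means,
#' at most `k_max` clusters per component) and combines the three component
#' maps into the categorical ELC map.
#'
#' @param stack An [eco_stack()].
#' @param selection Selection tibble from [select_final()] /
#'   [select_variables()].
#' @param seed Integer seed.
#' @param k_max Maximum clusters per component.
#' @param nstart K-means restarts per `k`.
#' @return A list with `elc` (the `elc_map`) and `clusterings` (named list
#'   of the three `component_clustering` fits).
#' @export
build_elc_map <- function(stack, selection, seed = 1L, k_max = 8, nstart = 10) {
  stack <- add_latlon_layers(stack)
  comps <- c("bioclimatic", "edaphic", "geophysic")
  fits <- purrr::map(stats::setNames(comps, comps), function(comp) {
    vars <- selection$variable[selection$component == comp]
    cluster_component(stack, comp,
      variables = vars, k_max = k_max,
      seed = derive_seed(seed, comp), nstart = nstart
    )
  })
  elc <- combine_components(
    fits$bioclimatic, fits$edaphic, fits$geophysic,
    stack = stack
  )
  list(elc = elc, clusterings = fits)
}
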