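#' Extract raster values at occurrence sites
#'
#' Containing-cell lookup of every layer of the stack at each record's
#' coordinates (half-open cell intervals; see [cell_index()]). Records
#' falling outside the grid or on a nodata cell are excluded from the
#' matrix and listed in the `excluded` attribute with a reason.
#'
#' @param stack An [eco_stack()].
#' @param records Occurrence tibble with `record_id`, `latitude`,
#'   `longitude`.
#' @return A tibble (`record_id`, `row`, `col`, then one column per layer)
#'   with attribute `excluded`: a tibble of `record_id`, `reason`
#'   (`"outside_extent"` or `"nodata_cell"`).
#' @export
extract_values <- function(stack, records) {
  idx <- cell_index(stack, records$longitude, records$latitude)
  outside <- is.na(idx$row)
  flat <- (idx$col - 1L) * stack$nrow + idx$row
  vals <- purrr::map(stack$layers, ~ .x[ifelse(outside, 1L, flat)])
  nod <- !outside & Reduce(`|`, purrr::map(vals, is.na))
  keep <- !outside & !nod
  out <- tibble::tibble(
    record_id = records$record_id[keep],
    row = idx$row[keep], col = idx$col[keep],
    !!!purrr::map(vals, ~ .x[keep])
  )
  attr(out, "excluded") <- tibble::tibble(
    record_id = records$record_id[!keep],
    reason = ifelse(outside[!keep], "outside_extent", "nodata_cell")
  )
  out
}

#' Rank variable importance by random forest
#'
#' Unsupervised random-forest contrast: a synthetic class of the same size
#' is built by independently permuting each column of the site x variable
#' matrix (destroying the joint structure while keeping the marginals), and
#' a random forest is trained to tell real rows from permuted rows.
#' Importance is the permutation importance (mean decrease in accuracy),
#' averaged over `n_rep` seeded repetitions. Variables that discriminate
#' adaptive scenarios — i.e. carry joint structure across sites — rank
#' first. Constant variables get importance 0 and sit at the tail.
#'
#' @param site_matrix Tibble from [extract_values()] (or any tibble whose
#'   variable columns are numeric).
#' @param variables Character vector of column names to rank (e.g. the
#'   layers of one ecogeographical component).
#' @param seed Integer seed; identical input and seed give identical
#'   rankings.
#' @param n_rep Number of forest repetitions averaged (>= 5 recommended).
#' @param ntree Trees per forest.
#' @return A tibble `variable`, `importance`, `rank`, sorted by importance
#'   descending (ties broken by variable name).
#' @export
rank_importance <- function(site_matrix, variables, seed = 1L,
                            n_rep = 5L, ntree = 500L) {
  x <- as.data.frame(site_matrix[, variables, drop = FALSE])
  if (ncol(x) < 2) stop("need at least 2 variables to rank", call. = FALSE)
  if (nrow(x) < 20) stop("need at least 20 records to rank importance", call. = FALSE)
  sds <- vapply(x, stats::sd, numeric(1))
  live <- names(x)[sds > 0]
  imp <- stats::setNames(numeric(length(variables)), variables)
  if (length(live) >= 2) {
    acc <- stats::setNames(numeric(length(live)), live)
    for (rep in seq_len(n_rep)) {
      set.seed(derive_seed(seed, paste0("rf_rep_", rep)))
      xl <- x[, live, drop = FALSE]
      x_perm <- as.data.frame(lapply(xl, sample))
      xx <- rbind(xl, x_perm)
      y <- factor(rep(c("real", "permuted"), each = nrow(xl)))
      rf <- randomForest::randomForest(
        x = xx, y = y, ntree = ntree, importance = TRUE
      )
      acc <- acc + randomForest::importance(rf, type = 1)[live, 1]
    }
    imp[live] <- acc / n_rep
  }
  imp[sds == 0] <- 0
  ord <- order(-imp, names(imp))
  tibble::tibble(
    variable = names(imp)[ord],
    importance = unname(imp[ord]),
    rank = seq_along(imp)
  )
}

#' Prune correlated variables from an importance ranking
#'
#' Restricts the ranking to its `top_n` variables, then scans pairs in rank
#' order: when two surviving variables have Pearson |r| above `r_threshold`
#' with a two-sided p-value (t statistic, n-2 df) below `alpha`, the
#' lower-ranked member is dropped. A dropped variable takes no further part
#' in the scan, so it can never drop others; the top-ranked variable can
#' never be dropped.
#'
#' @param ranking Tibble from [rank_importance()].
#' @param site_matrix The matrix the ranking was computed on.
#' @param top_n Ranking is truncated to this many variables before pruning.
#' @param r_threshold Absolute Pearson correlation above which a pair is
#'   redundant.
#' @param alpha Significance level for the correlation test.
#' @return The truncated ranking with columns `kept` (logical) and
#'   `dropped_by` (the variable that removed it, or `NA`); attribute
#'   `pruned_pairs` holds a tibble `kept_var`, `dropped_var`, `r`,
#'   `p_value`.
#' @export
prune_correlated <- function(ranking, site_matrix, top_n = 15,
                             r_threshold = 0.50, alpha = 0.05) {
  rk <- utils::head(ranking, top_n)
  vars <- rk$variable
  kept <- rep(TRUE, length(vars))
  dropped_by <- rep(NA_character_, length(vars))
  pairs <- list()
  for (i in seq_along(vars)) {
    if (!kept[i]) next
    for (j in seq_along(vars)) {
      if (j <= i || !kept[j]) next
      xi <- site_matrix[[vars[i]]]
      xj <- site_matrix[[vars[j]]]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- stats::cor.test(xi, xj, method = "pearson")
      if (abs(ct$estimate) > r_threshold && ct$p.value < alpha) {
        kept[j] <- FALSE
        dropped_by[j] <- vars[i]
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          kept_var = vars[i], dropped_var = vars[j],
          r = unname(ct$estimate), p_value = ct$p.value
        )
      }
    }
  }
  out <- dplyr::mutate(rk, kept = kept, dropped_by = dropped_by)
  attr(out, "pruned_pairs") <- dplyr::bind_rows(pairs)
  out
}

#' Assemble the final variable selection
#'
#' Takes the top surviving variables of each pruned component ranking —
#' by default three bioclimatic, three edaphic and two geophysic — and
#' appends `LATITUDE` and `LONGITUDE` as two additional geophysic
#' variables, which pulls the eventual map categories into spatially
#' aggregated patches. Components with fewer survivors than requested
#' contribute all their survivors, with a warning.
#'
#' @param pruned Named list of pruned rankings (from [prune_correlated()])
#'   with entries `bioclimatic`, `edaphic`, `geophysic`.
#' @param n_bioclimatic,n_edaphic,n_geophysic Variables taken per component.
#' @return A tibble `component`, `rank`, `variable` (the selection report).
#' @export
select_final <- function(pruned, n_bioclimatic = 3, n_edaphic = 3,
                         n_geophysic = 2) {
  want <- c(
    bioclimatic = n_bioclimatic, edaphic = n_edaphic, geophysic = n_geophysic
  )
  rows <- purrr::imap(want, function(n, comp) {
    surv <- dplyr::filter(pruned[[comp]], .data$kept)
    if (nrow(surv) < n) {
      rlang::warn(sprintf(
        "component %s has only %d surviving variables (%d requested)",
        comp, nrow(surv), n
      ))
    }
    take <- utils::head(surv, n)
    tibble::tibble(component = comp, variable = take$variable)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(
      component = "geophysic", variable = c("LATITUDE", "LONGITUDE")
    )
  )
  out |>
    dplyr::group_by(.data$component) |>
    dplyr::mutate(rank = dplyr::row_number(), .after = "component") |>
    dplyr::ungroup()
}

#' Select ecogeographical variables for a species
#'
#' End-to-end variable selection: extract layer values at the records'
#' sites, rank importance per component by random forest, prune correlated
#' variables within each component, and take the final per-component
#' selection (plus latitude/longitude as geophysic variables).
#'
#' @param stack An [eco_stack()].
#' @param records QC-passed occurrence tibble for one species.
#' @param seed Integer seed for the forests.
#' @param top_n,r_threshold,alpha See [prune_correlated()].
#' @param n_bioclimatic,n_edaphic,n_geophysic See [select_final()].
#' @return A list with `selection` (tibble from [select_final()]),
#'   `rankings` (per-component pruned rankings) and `site_matrix`.
#' @export
select_variables <- function(stack, records, seed = 1L, top_n = 15,
                             r_threshold = 0.50, alpha = 0.05,
                             n_bioclimatic = 3, n_edaphic = 3,
                             n_geophysic = 2) {
  sm <- extract_values(stack, records)
  comps <- c("bioclimatic", "edaphic", "geophysic")
  pruned <- purrr::map(stats::setNames(comps, comps), function(comp) {
    vars <- names(stack$component)[stack$component == comp]
    vars <- setdiff(vars, c("LATITUDE", "LONGITUDE"))
    rk <- rank_importance(sm, vars, seed = derive_seed(seed, comp))
    prune_correlated(rk, sm,
      top_n = top_n, r_threshold = r_threshold, alpha = alpha
    )
  })
  list(
    selection = select_final(pruned, n_bioclimatic, n_edaphic, n_geophysic),
    rankings = pruned,
    site_matrix = sm
  )
}
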