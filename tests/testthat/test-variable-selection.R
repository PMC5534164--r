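test_that("extraction uses the containing cell with half-open edges", {
  m <- matrix(as.numeric(1:4), 2, 2) # col-major: (1,1)=1 (2,1)=2 (1,2)=3 (2,2)=4
  st <- eco_stack(
    list(v = m), c(v = "bioclimatic"),
    xmin = 0, ymin = 0, cell_size = 1
  )
  rec <- make_records(
    lat = c(1.5, 0.5, 1.0, 2.5),
    lon = c(0.5, 1.5, 1.0, 0.5)
  )
  # (lat 1.5, lon 0.5) -> top-left cell; (1.0, 1.0) on the shared corner
  # belongs to the cell north-east of it (half-open intervals)
  out <- extract_values(st, rec)
  expect_equal(out$v, c(1, 4, 3))
  excl <- attr(out, "excluded")
  expect_identical(excl$record_id, "R004")
  expect_identical(excl$reason, "outside_extent")
})

test_that("records on nodata cells are excluded and reported", {
  m <- matrix(c(NA, 1, 2, 3), 2, 2)
  st <- eco_stack(list(v = m), c(v = "edaphic"), 0, 0, 1)
  rec <- make_records(lat = c(1.5, 0.5), lon = c(0.5, 0.5))
  out <- extract_values(st, rec)
  expect_identical(out$record_id, "R002")
  expect_identical(attr(out, "excluded")$reason, "nodata_cell")
})

test_that("zero-noise extraction returns the exact zone mean", {
  land <- generate_raster_stack(small_spec(seed = 41, noise_sd = 0))
  occ <- sample_occurrences(land$truth, 0, 30, seed = 9)
  rec <- parse_occurrences(occ)
  out <- extract_values(land$stack, rec)
  lbl <- land$truth$component_labels$bioclimatic
  mu <- land$truth$zone_means$bioclimatic
  zone <- lbl[cbind(out$row, out$col)]
  expect_equal(out$annual_precipitation, mu[zone, "annual_precipitation"],
    ignore_attr = TRUE
  )
})

test_that("informative variables outrank noise and constants rank zero", {
  spec <- small_spec(
    seed = 43,
    n_informative = c(bioclimatic = 2, edaphic = 2, geophysic = 1)
  )
  land <- generate_raster_stack(spec)
  occ <- sample_occurrences(land$truth, 0, 150, seed = 10)
  sm <- extract_values(land$stack, parse_occurrences(occ))
  sm$flat <- 1.0 # constant column
  vars <- c("bio03", "bio04", "annual_precipitation", "annual_mean_temperature", "flat")
  rk <- rank_importance(sm, vars, seed = 5)
  expect_identical(rk$variable[rk$importance == 0], "flat")
  # zone-defining variables (the two designated ones) beat the noise pair
  info <- c("annual_precipitation", "annual_mean_temperature")
  expect_true(all(rk$rank[rk$variable %in% info] <= 2))
  # determinism
  rk2 <- rank_importance(sm, vars, seed = 5)
  expect_identical(rk, rk2)
})

test_that("preconditions on matrix size are enforced", {
  sm <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  expect_error(rank_importance(sm, c("a", "b")), "at least 20")
  sm2 <- tibble::tibble(a = rnorm(30))
  expect_error(rank_importance(sm2, "a"), "at least 2")
})

test_that("pruning drops the lower-ranked member of a correlated pair only", {
  set.seed(77)
  n <- 200
  a <- rnorm(n)
  sm <- tibble::tibble(
    a = a,
    b = a + rnorm(n, sd = 0.2), # r ~ 0.98 with a
    c = rnorm(n) # independent
  )
  rk <- tibble::tibble(variable = c("a", "c", "b"), importance = c(3, 2, 1), rank = 1:3)
  out <- prune_correlated(rk, sm)
  expect_identical(out$kept, c(TRUE, TRUE, FALSE))
  expect_identical(out$dropped_by[3], "a")
  pp <- attr(out, "pruned_pairs")
  expect_gt(abs(pp$r), 0.5)
  expect_lt(pp$p_value, 0.05)
})

test_that("a pair below the correlation threshold is untouched", {
  set.seed(78)
  n <- 400
  a <- rnorm(n)
  sm <- tibble::tibble(a = a, b = 0.3 * a + rnorm(n)) # r ~ 0.29
  rk <- tibble::tibble(variable = c("a", "b"), importance = 2:1, rank = 1:2)
  out <- prune_correlated(rk, sm)
  expect_true(all(out$kept))
})

test_that("with three mutually correlated variables only the leader survives", {
  set.seed(79)
  n <- 300
  base <- rnorm(n)
  sm <- tibble::tibble(
    v1 = base + rnorm(n, sd = 0.1),
    v2 = base + rnorm(n, sd = 0.1),
    v3 = base + rnorm(n, sd = 0.1)
  )
  rk <- tibble::tibble(variable = c("v1", "v2", "v3"), importance = 3:1, rank = 1:3)
  out <- prune_correlated(rk, sm)
  expect_identical(out$kept, c(TRUE, FALSE, FALSE))
  # v2 was dropped by v1 and can no longer drop v3: both droppings credit v1
  expect_identical(unique(na.omit(out$dropped_by)), "v1")
})

test_that("the final selection is 3 + 3 + (2 + lat/lon) with warnings when short", {
  mk <- function(vars) {
    tibble::tibble(
      variable = vars, importance = rev(seq_along(vars)),
      rank = seq_along(vars), kept = TRUE, dropped_by = NA_character_
    )
  }
  pruned <- list(
    bioclimatic = mk(c("b1", "b2", "b3", "b4")),
    edaphic = mk(c("e1", "e2", "e3")),
    geophysic = mk(c("g1", "g2"))
  )
  sel <- select_final(pruned)
  expect_identical(nrow(sel), 3L + 3L + 4L)
  expect_identical(
    sel$variable[sel$component == "geophysic"],
    c("g1", "g2", "LATITUDE", "LONGITUDE")
  )

  pruned$geophysic <- mk("g1")
  expect_warning(sel2 <- select_final(pruned), "geophysic")
  expect_identical(
    sel2$variable[sel2$component == "geophysic"],
    c("g1", "LATITUDE", "LONGITUDE")
  )
})

test_that("zone-defining variables reach the final set across seeds", {
  hits <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    spec <- small_spec(
      seed = 100 + s,
      n_informative = c(bioclimatic = 2, edaphic = 2, geophysic = 1)
    )
    land <- generate_raster_stack(spec)
    occ <- sample_occurrences(land$truth, 0, 120, seed = 200 + s)
    # a pruned-away noise variable can legitimately leave a component short
    res <- suppressWarnings(
      select_variables(land$stack, parse_occurrences(occ), seed = 300 + s)
    )
    info <- c(
      "annual_precipitation", "annual_mean_temperature", # bioclimatic
      "topsoil_salinity", "eda02", # edaphic
      "geo01" # geophysic
    )
    if (all(info %in% res$selection$variable)) hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_seeds))
})
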