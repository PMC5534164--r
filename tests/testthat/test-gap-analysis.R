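# A tiny hand-built ELC map used across the gap tests: 4 x 5 grid, four
# categories with known cell counts (category 4 is the rarest).
toy_elc <- function() {
  cat_m <- matrix(NA_integer_, 4, 5)
  cat_m[1:4, 1:2] <- 1L # 8 cells
  cat_m[1:4, 3] <- 2L # 4 cells
  cat_m[1:3, 4] <- 3L # 3 cells
  cat_m[c(1, 2), 5] <- 4L # 2 cells
  legend <- tibble::tibble(
    category = 1:4,
    bioclimatic = c(1L, 1L, 2L, 2L), edaphic = c(1L, 2L, 1L, 2L),
    geophysic = 1L,
    n_cells = c(8L, 4L, 3L, 2L)
  )
  legend$territory_share <- legend$n_cells / sum(legend$n_cells)
  structure(
    list(
      category = cat_m, legend = legend,
      geom = list(xmin = 0, ymin = 0, cell_size = 1, nrow = 4, ncol = 5)
    ),
    class = "elc_map"
  )
}

# one record per listed category, centred in a cell of that category
records_in_categories <- function(cats, source_class, prefix = "R") {
  cell_for <- list(
    `1` = c(3.5, 0.5), `2` = c(3.5, 2.5), `3` = c(3.5, 3.5), `4` = c(3.5, 4.5)
  )
  pts <- do.call(rbind, lapply(as.character(cats), function(ct) cell_for[[ct]]))
  make_records(
    lat = pts[, 1], lon = pts[, 2], source_class = source_class,
    record_id = sprintf("%s%03d", prefix, seq_along(cats))
  )
}

test_that("spatial gaps are externals farther than 1 km from every accession", {
  acc <- make_records(c(40, 41), c(0, 0), source_class = "accession")
  ext <- make_records(
    c(40, offset_north_km(40, 1.5), offset_north_km(41, 0.2)),
    c(0, 0, 0),
    record_id = c("E1", "E2", "E3")
  )
  out <- spatial_gaps(dplyr::bind_rows(acc, ext))
  expect_identical(out$is_spatial_gap[match(c("E1", "E2", "E3"), out$record_id)],
    c(FALSE, TRUE, FALSE))

  # species without accessions: everything is a gap
  lone <- make_records(c(40, 41), c(2, 2), species = "Lonely sp")
  out2 <- spatial_gaps(lone)
  expect_true(all(out2$is_spatial_gap))
})

test_that("spatial gaps equal the brute-force all-pairs oracle", {
  set.seed(31)
  n_a <- 60
  n_e <- 300
  acc <- make_records(40 + runif(n_a, 0, 0.2), runif(n_a, 0, 0.2),
    source_class = "accession", record_id = sprintf("A%03d", 1:n_a)
  )
  ext <- make_records(40 + runif(n_e, 0, 0.2), runif(n_e, 0, 0.2),
    record_id = sprintf("E%03d", 1:n_e)
  )
  out <- spatial_gaps(dplyr::bind_rows(acc, ext))
  oracle <- vapply(seq_len(n_e), function(i) {
    all(haversine_km(ext$latitude[i], ext$longitude[i],
      acc$latitude, acc$longitude) > 1)
  }, logical(1))
  expect_identical(out$is_spatial_gap[match(ext$record_id, out$record_id)], oracle)
})

test_that("gap categories are exactly those with externals but no accessions", {
  elc <- toy_elc()
  recs <- dplyr::bind_rows(
    records_in_categories(c(1, 2), "accession", "A"),
    records_in_categories(c(2, 3, 4), "external", "E")
  )
  recs <- assign_category(elc, recs)
  rp <- representativeness(elc, recs)
  expect_identical(rp$n_categories, 4L)
  expect_identical(rp$represented, c(1L, 2L))
  expect_identical(rp$gap_categories, c(3L, 4L))
  # oracle by direct set algebra
  acc_set <- unique(recs$elc_category[recs$source_class == "accession"])
  ext_set <- unique(recs$elc_category[recs$source_class == "external"])
  expect_setequal(rp$gap_categories, setdiff(ext_set, acc_set))
})

test_that("priority ranks are 1-4 exactly for unrepresented categories", {
  elc <- toy_elc()
  recs <- dplyr::bind_rows(
    records_in_categories(c(1, 1, 2), "accession", "A"),
    records_in_categories(c(1, 2, 3, 4, 4), "external", "E")
  )
  recs <- assign_category(elc, recs)
  rp <- representativeness(elc, recs)
  ext <- dplyr::filter(recs, source_class == "external")
  rk <- priority_rank(ext, rp)
  expect_identical(rk$is_priority_gap, rk$elc_category %in% c(3L, 4L))
  expect_true(all(rk$priority_rank[rk$is_priority_gap] <= 4))
  expect_true(all(rk$priority_rank[!rk$is_priority_gap] >= 5))
  # category 4 is rarer than 3: it gets the lower (more urgent) rank
  r3 <- unique(rk$priority_rank[rk$elc_category == 3])
  r4 <- unique(rk$priority_rank[rk$elc_category == 4])
  expect_lt(r4, r3)
})

test_that("category-0 records are excluded from ranking with a warning", {
  elc <- toy_elc()
  recs <- records_in_categories(c(3, 4), "external", "E")
  recs <- assign_category(elc, recs)
  recs$elc_category[1] <- 0L
  rp <- representativeness(elc, recs)
  expect_warning(rk <- priority_rank(recs, rp), "not rankable")
  expect_identical(nrow(rk), 1L)
})

test_that("improvement percentages reproduce the published arithmetic", {
  expect_equal(improvement_stats(27, 13, 12)$current_pct, 48)
  expect_equal(improvement_stats(27, 7, 19)$improvement_pct, 70)
  expect_equal(improvement_stats(26, 2, 7)$improvement_pct, 27)
  expect_equal(improvement_stats(26, 2, 7)$current_pct, 8)
  expect_error(improvement_stats(0, 0, 0), "positive")
  expect_error(improvement_stats(10, 8, 5), "exceed")
})

test_that("the gap report sums species counts and rounds percentages half-up", {
  mk_ranked <- function(n, n_gap, n_spatial) {
    tibble::tibble(
      record_id = sprintf("r%d", seq_len(n)),
      elc_category = 1L,
      is_spatial_gap = seq_len(n) <= n_spatial,
      is_priority_gap = seq_len(n) <= n_gap
    )
  }
  ranked <- list(
    sp1 = mk_ranked(15, 12, 15),
    sp2 = mk_ranked(100, 10, 95)
  )
  reps <- list(
    sp1 = structure(list(
      n_categories = 26L, represented = 1:2, gap_categories = 3:9,
      freq = tibble::tibble(category = 1:26, territory_share = 1 / 26,
        accession_share = 0, external_share = 0)
    ), class = "representativeness"),
    sp2 = structure(list(
      n_categories = 27L, represented = 1:13, gap_categories = 14:25,
      freq = tibble::tibble(category = 1:27, territory_share = 1 / 27,
        accession_share = 0, external_share = 0)
    ), class = "representativeness")
  )
  out <- gap_report(ranked, reps)
  sp1 <- out$gaps[out$gaps$species == "sp1", ]
  expect_equal(sp1$pct_priority, 80) # 12 of 15
  tot <- out$gaps[out$gaps$species == "TOTAL", ]
  expect_equal(tot$n_priority_gaps, 22)
  expect_equal(tot$n_external, 115)
})

test_that("conserving a gap category removes it from the gap set", {
  elc <- toy_elc()
  recs <- dplyr::bind_rows(
    records_in_categories(c(1, 2), "accession", "A"),
    records_in_categories(c(3, 4), "external", "E")
  )
  recs <- assign_category(elc, recs)
  before <- representativeness(elc, recs)
  expect_identical(before$gap_categories, c(3L, 4L))

  new_acc <- assign_category(elc, records_in_categories(3, "accession", "N"))
  after <- representativeness(elc, dplyr::bind_rows(recs, new_acc))
  expect_identical(after$gap_categories, 4L)
  expect_lte(length(after$gap_categories), length(before$gap_categories))
})
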