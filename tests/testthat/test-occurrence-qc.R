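test_that("parsing preserves declared decimal counts from the text", {
  tbl <- tibble::tibble(
    RECORD_ID = c("a", "b", "c", "d"),
    SPECIES = "Sp", SOURCE_CLASS = "external",
    DECLATITUDE = c("41.700833", "41.7", "42", ""),
    DECLONGITUDE = c("−0.045000", "-0.1", "1.25", "3.0"),
    LOCALITY = "loc"
  )
  rec <- parse_occurrences(tbl)
  expect_identical(rec$dec_lat, c(6L, 1L, 0L, NA_integer_))
  expect_identical(rec$dec_lon, c(6L, 1L, 2L, 1L))
  expect_equal(rec$longitude[1], -0.045) # Unicode minus accepted
  expect_identical(rec$qc_status, c(rep("retained", 3), "removed_no_coords"))
})

test_that("missing mandatory columns are reported by name", {
  expect_error(
    parse_occurrences(tibble::tibble(RECORD_ID = "x", SPECIES = "y")),
    "SOURCE_CLASS.*DECLATITUDE|DECLATITUDE"
  )
})

test_that("the published 45-population shortlist parses completely", {
  path <- system.file("extdata", "aegilops_pc_subset.csv", package = "elcgap")
  rec <- parse_occurrences(path)
  expect_identical(nrow(rec), 45L)
  expect_identical(sum(rec$qc_status == "retained"), 45L)
  expect_true(all(rec$dec_lat >= 2 & rec$dec_lon >= 2))
  expect_identical(length(unique(rec$species)), 5L)
})

test_that("precision filter applies the three-way removal rule to externals only", {
  tbl <- tibble::tibble(
    RECORD_ID = sprintf("r%d", 1:6),
    SPECIES = "Sp",
    SOURCE_CLASS = c(rep("external", 5), "accession"),
    DECLATITUDE = c("41.7", "41.70", "41.700", "41.70", "41.70", "41.7"),
    DECLONGITUDE = c("-0.0", "-0.1", "-0.100", "-0.10", "-0.10", "-0.0"),
    COORD_SYSTEM = c("DD", "DD", "DD", "DD", "UTM", "DD"),
    UTM_RESOLUTION_M = c(NA, NA, NA, NA, "10000", NA),
    LOCALITY = c("here", "here", "", "here", "here", "")
  )
  rec <- precision_filter(parse_occurrences(tbl))
  removed <- rec$record_id[rec$qc_status == "removed_low_precision"]
  # r1: <2 decimals in both; r3: no locality; r5: 10x10 km UTM
  expect_setequal(removed, c("r1", "r3", "r5"))
  # r2: one coarse axis only; r6: accession, never removed
  expect_true(all(c("r2", "r4", "r6") %in% rec$record_id[rec$qc_status == "retained"]))
})

test_that("haversine matches the closed form, is symmetric and zero at identity", {
  expect_equal(haversine_km(0, 0, 0, 1), 6371.0088 * pi / 180, tolerance = 1e-12)
  expect_identical(haversine_km(41.2, -3.1, 41.2, -3.1), 0)
  set.seed(99)
  a_lat <- runif(50, -80, 80)
  a_lon <- runif(50, -179, 179)
  b_lat <- runif(50, -80, 80)
  b_lon <- runif(50, -179, 179)
  expect_equal(
    haversine_km(a_lat, a_lon, b_lat, b_lon),
    haversine_km(b_lat, b_lon, a_lat, a_lon)
  )
  skip_if_not_installed("geosphere")
  expect_equal(
    haversine_km(a_lat, a_lon, b_lat, b_lon),
    geosphere::distHaversine(cbind(a_lon, a_lat), cbind(b_lon, b_lat),
      r = 6371008.8
    ) / 1000,
    tolerance = 1e-9
  )
})

test_that("dedup keeps the higher-quality twin and respects the strict 1 km rule", {
  # two records 0.5 km apart: the better-scored one survives
  rec <- make_records(c(40, offset_north_km(40, 0.5)), c(0, 0),
    quality = c(60, 90)
  )
  out <- dedup_spatial(rec)
  expect_identical(out$qc_status, c("removed_duplicate", "retained"))

  # records exactly 1.0 km apart are NOT duplicates
  rec2 <- make_records(c(40, offset_north_km(40, 1.0)), c(0, 0))
  expect_identical(unique(dedup_spatial(rec2)$qc_status), "retained")

  # chain A-B-C at 0.8 km spacing: greedy keeps A and C (ids break the tie)
  lat <- c(40, offset_north_km(40, 0.8), offset_north_km(40, 1.6))
  rec3 <- make_records(lat, c(0, 0, 0), record_id = c("A", "B", "C"))
  out3 <- dedup_spatial(rec3)
  expect_identical(out3$qc_status[out3$record_id %in% c("A", "C")], rep("retained", 2))
  expect_identical(out3$qc_status[out3$record_id == "B"], "removed_duplicate")
})

test_that("dedup is idempotent and intraspecific within source class", {
  set.seed(42)
  n <- 300
  rec <- make_records(
    lat = 40 + runif(n, 0, 0.05), lon = runif(n, 0, 0.05),
    species = sample(c("sp1", "sp2"), n, replace = TRUE),
    source_class = sample(c("accession", "external"), n, replace = TRUE)
  )
  once <- dedup_spatial(rec)
  twice <- dedup_spatial(once)
  expect_identical(once$qc_status, twice$qc_status)

  # a cross-species pair 0 km apart must both survive
  pair <- make_records(c(40, 40), c(0, 0), species = c("sp1", "sp2"))
  expect_identical(unique(dedup_spatial(pair)$qc_status), "retained")
})

test_that("dedup satisfies its contract against a brute-force oracle", {
  set.seed(7)
  n <- 500
  rec <- make_records(lat = 40 + runif(n, 0, 0.08), lon = runif(n, 0, 0.08))
  out <- dedup_spatial(rec)
  kept <- out[out$qc_status == "retained", ]
  gone <- out[out$qc_status == "removed_duplicate", ]
  dmat <- outer(seq_len(nrow(kept)), seq_len(nrow(kept)), function(i, j) {
    haversine_km(kept$latitude[i], kept$longitude[i], kept$latitude[j], kept$longitude[j])
  })
  diag(dmat) <- Inf
  expect_true(all(dmat >= 1)) # retained pairwise >= 1 km
  for (i in seq_len(nrow(gone))) {
    d <- haversine_km(gone$latitude[i], gone$longitude[i], kept$latitude, kept$longitude)
    expect_lt(min(d), 1) # every removed record sits near a retained one
  }
})

test_that("quality scoring is maximal for precise, documented, matching records", {
  ring <- matrix(c(-1, 39, 1, 39, 1, 41, -1, 41), ncol = 2, byrow = TRUE)
  admin <- tibble::tibble(level = "adm3", name = "C", ring = list(ring))
  rec <- make_records(40, 0)
  scored <- score_georeferencing_quality(rec, admin)
  expect_equal(scored$quality_score, 100)

  # point outside its declared municipality: admin sub-score 0, total <= 67
  rec_out <- make_records(45, 10)
  scored_out <- score_georeferencing_quality(rec_out, admin)
  expect_lte(scored_out$quality_score, 67)
})

test_that("degrading coordinate precision never raises the quality score", {
  base <- make_records(rep(40.123456, 7), rep(0.654321, 7))
  base$dec_lat <- c(6L, 5L, 4L, 3L, 2L, 1L, 0L)
  base$dec_lon <- base$dec_lat
  scored <- suppressWarnings(score_georeferencing_quality(base))
  expect_true(all(diff(scored$quality_score) <= 0))
})

test_that("qc statuses partition the input and the report adds up", {
  land <- generate_raster_stack(small_spec(seed = 31))
  occ <- sample_occurrences(land$truth, 25, 150,
    dup_fraction = 0.2, degrade_fraction = 0.3, seed = 8
  )
  rec <- suppressWarnings(qc_pipeline(parse_occurrences(occ)))
  expect_identical(nrow(rec), nrow(occ))
  expect_true(all(rec$qc_status %in% c(
    "retained", "removed_no_coords", "removed_low_precision", "removed_duplicate"
  )))
  rep_tbl <- qc_report(rec)
  expect_equal(
    rep_tbl$n_initial,
    rep_tbl$n_low_precision + rep_tbl$n_duplicates +
      rep_tbl$n_quality_le + rep_tbl$n_quality_gt
  )
})

test_that("report percentages use round-half-up of the initial count", {
  rec <- dplyr::bind_rows(
    make_records(40 + seq(0, 0.29, by = 0.01) * 2, rep(0, 30)), # 30 externals
    make_records(seq(41, 41.29, by = 0.01) * 1, rep(5, 30),
      source_class = "accession"
    )
  )
  # force 13 externals into the low-precision bucket: 13/30 -> 43%
  rec$qc_status[1:13] <- "removed_low_precision"
  rec$quality_pass <- rec$qc_status == "retained"
  out <- qc_report(rec)
  ext <- out[out$source_class == "external", ]
  expect_equal(ext$pct_low_precision, 43)
  acc <- out[out$source_class == "accession", ]
  expect_equal(acc$pct_low_precision, 0)
})
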