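# Shared fixtures: small synthetic landscapes and hand-built record tables.

small_spec <- function(seed = 1L, noise_sd = 0.2, ...) {
  landscape_spec(
    extent = c(0, 1 / 3, 40, 40 + 1 / 3), # 40 x 40 cells at 30 arc-sec
    n_vars = c(bioclimatic = 4, edaphic = 3, geophysic = 2),
    true_k = c(bioclimatic = 3, edaphic = 3, geophysic = 3),
    noise_sd = noise_sd,
    seed = seed,
    ...
  )
}

# records tibble from bare coordinates, defaults chosen to pass QC
make_records <- function(lat, lon, species = "Test sp",
                         source_class = "external",
                         quality = 100,
                         record_id = sprintf("R%03d", seq_along(lat))) {
  tibble::tibble(
    record_id = record_id,
    species = species,
    source_class = source_class,
    latitude = lat, longitude = lon,
    lat_text = sprintf("%.6f", lat), lon_text = sprintf("%.6f", lon),
    dec_lat = 6L, dec_lon = 6L,
    coord_system = "DD", utm_resolution_m = NA_real_,
    locality = "somewhere", country = "Testland",
    adm1 = "A", adm2 = "B", adm3 = "C",
    qc_status = "retained",
    quality_score = quality,
    elc_category = 0L
  )
}

# move a point a given distance (km) north; inverse of haversine on a sphere
offset_north_km <- function(lat, km) lat + km / (6371.0088 * pi / 180)

# one-layer-per-component stack from three label matrices (plus values)
stack_from_matrices <- function(layers, component, xmin = 0, ymin = 40,
                                cell_size = 0.01) {
  eco_stack(layers, component, xmin, ymin, cell_size)
}
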