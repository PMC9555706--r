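# Shared fixtures, generated in code. Heavier fixtures are built lazily and
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

hourly_stamps <- function(n, start = "2020-01-01 00:00:00", tz = "UTC") {
  seq(as.POSIXct(start, tz = tz), by = 3600, length.out = n)
}

# n sites on a small irregular grid with both tiers represented
toy_sites <- function(n = 5) {
  set.seed(400 + n)
  data.frame(
    site_id = sprintf("s%02d", seq_len(n)),
    x_km = runif(n, 0, 20), y_km = runif(n, 0, 20),
    tier = rep(c("reference", "low_cost"), length.out = n),
    stringsAsFactors = FALSE
  )
}

toy_dist <- function(sites) build_geometry(sites)$dist

# panel whose every (site, slot) series is an exact known cubic
cubic_panel <- function(n_sites = 3, n_days = 20, coef = NULL, tz = "UTC") {
  stamps <- hourly_stamps(n_days * 24, tz = tz)
  hod <- as.integer(format(stamps, "%H", tz = tz))
  slot <- hod %/% 8L + 1L
  tin <- hod - 8L * (slot - 1L)
  if (is.null(coef)) {
    coef <- matrix(c(0.5, -2, 3, 100,
                     -0.3, 1, -2, 150,
                     0.1, 0.5, 1, 120), 3, 4, byrow = TRUE)
  }
  base <- coef[slot, 1] * tin^3 + coef[slot, 2] * tin^2 +
    coef[slot, 3] * tin + coef[slot, 4]
  vals <- do.call(rbind, lapply(seq_len(n_sites), function(i) base + 7 * (i - 1)))
  rownames(vals) <- sprintf("s%02d", seq_len(n_sites))
  list(panel = readings_panel(vals, stamps, bounds = NULL), coef = coef,
       slot = slot, tin = tin)
}

# small synthetic city reused across evaluate/pipeline tests
toy_city <- function() {
  cached("toy_city", simulate_city(sim_config(n_sites = 8, n_days = 40, seed = 99)))
}

# tiny profile overrides so every pipeline preset runs in seconds
tiny_overrides <- function() {
  list(epochs = 2, stride = 6, sthm = list(max_iter = 4, tol = 1e-3))
}
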