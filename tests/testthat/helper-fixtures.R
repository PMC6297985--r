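# Shared fixture builders for the test suite. Everything is generated
# in code; no binary fixtures.

# default 40-L / 10-L-min plant cuvette (tau = 4 min)
fix_cfg <- function(id = "c1", volume = 40, flow = 10, area = 0.1,
                    role = "plant") {
  cuvette_config(id, volume, flow, role,
                 leaf_area_m2 = if (role == "plant") area else 0)
}

# build a regular multiplexed log visiting `ids` in order, `n_cycles`
# times, one record per `by` seconds per channel
fix_log <- function(ids, dwell = 300, n_cycles = 2, by = 1,
                    channels = "voc",
                    value_fun = function(t, id, ch) rep(1, length(t))) {
  rows <- list()
  for (k in seq_len(n_cycles) - 1L) {
    for (j in seq_along(ids)) {
      start <- k * length(ids) * dwell + (j - 1L) * dwell
      t <- seq(start, start + dwell - by, by = by)
      for (ch in channels)
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t, active_cuvette = ids[j], channel = ch,
          value = value_fun(t, ids[j], ch))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$time_s, out$channel), ]
}

fix_series <- function(t, v, id = "c1", comp = "voc") conc_series(id, comp, t, v)

# deterministic uniform draw helper for property loops
fix_runif <- function(n, lo, hi, seed) {
  set.seed(seed)
  lo + (hi - lo) * runif(n)
}
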