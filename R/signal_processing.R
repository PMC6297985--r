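# Demultiplexing of valve-switched sensor logs, lag-time discard, and
# empty-cuvette cubic-spline background correction.

#' Demultiplex a valve-switched sensor log into per-cuvette series
#'
#' Downstream analyzers sample one cuvette at a time; this splits the
#' interleaved log by active cuvette and channel, discarding every record
#' acquired within `schedule$lag_s` seconds after a valve switch (the gas
#' exchange time of the tubing between cuvette outlet and sensor).
#'
#' Valve-switch times are reconstructed from changes in the
#' `active_cuvette` column when present; otherwise from the schedule's
#' nominal timing starting at `schedule$start_time_s`.
#'
#' @param log A data.frame with columns `time_s`, `channel`, `value` and
#'   (normally) `active_cuvette`; timestamps non-decreasing.
#' @param schedule A [valve_schedule()].
#' @return A list with `series` (nested list
#'   `series[[cuvette_id]][[channel]]`, each a [conc_series()]),
#'   `kept` / `discarded` (record counts), and `counts` (a data.frame of
#'   kept/discarded per channel).
#' @examples
#' sched <- valve_schedule(c("a", "b"), dwell_s = 10, lag_s = 2)
#' log <- data.frame(time_s = 0:19,
#'                   active_cuvette = rep(c("a", "b"), each = 10),
#'                   channel = "voc", value = 1:20)
#' d <- demultiplex(log, sched)
#' d$discarded  # 2 records per dwell window
#' @export
demultiplex <- function(log, schedule) {
  if (!inherits(schedule, "valve_schedule"))
    cf_stop_input("`schedule` must be a valve_schedule")
  log <- as.data.frame(log)
  need <- c("time_s", "channel", "value")
  if (!all(need %in% names(log)))
    cf_stop_validation(sprintf("log must have columns %s",
                               paste(need, collapse = ", ")))
  if (nrow(log) == 0L)
    cf_stop_input("empty log")
  if (is.unsorted(log$time_s))
    cf_stop_validation("log timestamps must be non-decreasing")

  if ("active_cuvette" %in% names(log)) {
    active <- as.character(log$active_cuvette)
    unknown <- setdiff(unique(active), schedule$cuvette_order)
    if (length(unknown))
      cf_stop_validation(sprintf("log references cuvette id(s) not in schedule: %s",
                                 paste(unknown, collapse = ", ")))
    # switch happens whenever the annotated active cuvette changes
    run <- rle(active)
    run_id <- rep.int(seq_along(run$lengths), run$lengths)
    switch_time <- log$time_s[c(1L, 1L + cumsum(head(run$lengths, -1L)))]
    since_switch <- log$time_s - switch_time[run_id]
  } else {
    # nominal timing: dwell windows of dwell_s starting at start_time_s
    rel <- log$time_s - schedule$start_time_s
    if (any(rel < 0))
      cf_stop_validation("log starts before schedule start_time_s and has no active_cuvette column")
    slot <- floor(rel / schedule$dwell_s)
    idx <- (slot %% length(schedule$cuvette_order)) + 1L
    active <- schedule$cuvette_order[idx]
    since_switch <- rel - slot * schedule$dwell_s
  }

  keep <- since_switch >= schedule$lag_s
  counts <- stats::aggregate(keep, by = list(channel = log$channel),
                             FUN = function(k) c(kept = sum(k), discarded = sum(!k)))
  counts <- data.frame(channel = counts$channel,
                       kept = counts$x[, "kept"],
                       discarded = counts$x[, "discarded"])

  kept_log <- log[keep, , drop = FALSE]
  kept_active <- active[keep]
  series <- list()
  for (cid in schedule$cuvette_order) {
    sel <- kept_active == cid
    if (!any(sel)) next
    sub <- kept_log[sel, , drop = FALSE]
    per_chan <- split(sub, sub$channel, drop = TRUE)
    series[[cid]] <- lapply(per_chan, function(df) {
      # collapse duplicate timestamps (several sensors logging the same
      # second) by their mean to keep the series strictly increasing
      if (anyDuplicated(df$time_s)) {
        agg <- stats::aggregate(df$value, by = list(time_s = df$time_s), FUN = mean)
        conc_series(cid, df$channel[1L], agg$time_s, agg$x)
      } else {
        conc_series(cid, df$channel[1L], df$time_s, df$value)
      }
    })
  }
  list(series = series, kept = sum(keep), discarded = sum(!keep),
       counts = counts)
}

# pool several series, average values at (numerically) shared
# timestamps, return sorted (time, value)
pool_series <- function(series_list) {
  tt <- unlist(lapply(series_list, `[[`, "time_s"))
  vv <- unlist(lapply(series_list, `[[`, "value"))
  o <- order(tt)
  tt <- tt[o]; vv <- vv[o]
  key <- round(tt, 6)
  if (anyDuplicated(key)) {
    agg_t <- tapply(tt, key, mean)
    agg_v <- tapply(vv, key, mean)
    o2 <- order(as.numeric(agg_t))
    tt <- as.numeric(agg_t)[o2]; vv <- as.numeric(agg_v)[o2]
  }
  list(time_s = tt, value = vv)
}

# cubic-spline interpolator through pooled background points.
# FMM end conditions ("fmm") reproduce cubic polynomials exactly, which
# natural end conditions cannot; queries outside the background range
# are held at the endpoint values (no extrapolation).
spline_interp_held <- function(time_s, value, query_s, method = "fmm") {
  if (length(time_s) == 1L) return(rep_len(value, length(query_s)))
  if (length(time_s) < 4L) {
    return(approx(time_s, value, xout = pmin(pmax(query_s, min(time_s)),
                                             max(time_s)), rule = 2)$y)
  }
  sf <- splinefun(time_s, value, method = method)
  sf(pmin(pmax(query_s, min(time_s)), max(time_s)))
}

#' Subtract the empty-cuvette background from a concentration series
#'
#' Empty cuvettes flushed with the same supply air carry the system's
#' contaminant signal (tubing outgassing, supply-air drift). Their
#' demultiplexed series are averaged (cycle-by-cycle: values sharing a
#' timestamp are averaged, the rest pooled), interpolated with a cubic
#' spline over time, evaluated at the target's timestamps and
#' subtracted. Negative corrected values are retained — clipping would
#' bias emission-rate averages — and counted in the `n_negative`
#' attribute.
#'
#' @param target A [conc_series()] to correct.
#' @param backgrounds A list of one or more background `conc_series`
#'   (a bare `conc_series` is accepted and wrapped).
#' @param cycle_s Optional multiplex cycle length in seconds; when given,
#'   background coverage gaps longer than two cycles trigger a warning
#'   (the spline holds its endpoint values rather than extrapolating).
#' @param method Spline method passed to [stats::splinefun()]; the
#'   default `"fmm"` reproduces polynomial backgrounds up to degree 3
#'   exactly.
#' @return A `conc_series` on the target's timestamps with attributes
#'   `n_negative` and `background_range`.
#' @export
background_correct <- function(target, backgrounds, cycle_s = NULL,
                               method = "fmm") {
  if (!inherits(target, "conc_series"))
    cf_stop_input("`target` must be a conc_series")
  if (inherits(backgrounds, "conc_series")) backgrounds <- list(backgrounds)
  if (!is.list(backgrounds) || length(backgrounds) == 0L)
    cf_stop(paste0("`backgrounds` must be a non-empty list of conc_series; ",
                   "configure at least one empty_background cuvette"),
            "cf_configuration_error")
  ok <- vapply(backgrounds, inherits, logical(1), what = "conc_series")
  if (!all(ok))
    cf_stop_input("every background must be a conc_series")

  pooled <- pool_series(backgrounds)
  if (!is.null(cycle_s)) {
    gaps <- diff(pooled$time_s)
    cover_lo <- min(target$time_s) - min(pooled$time_s)
    cover_hi <- max(target$time_s) - max(pooled$time_s)
    if ((length(gaps) && max(gaps) > 2 * cycle_s) ||
        cover_lo < -2 * cycle_s || cover_hi > 2 * cycle_s)
      warning(sprintf(paste0("background coverage gap exceeds 2 multiplex ",
                             "cycles (%g s); endpoint values held, no ",
                             "extrapolation"), 2 * cycle_s),
              call. = FALSE)
  }
  bg_at_target <- spline_interp_held(pooled$time_s, pooled$value,
                                     target$time_s, method = method)
  out <- conc_series(target$cuvette_id, target$compound_id,
                     target$time_s, target$value - bg_at_target)
  attr(out, "n_negative") <- sum(out$value < 0)
  attr(out, "background_range") <- range(pooled$time_s)
  out
}

#' Pair an outlet series with its inlet measurement
#'
#' The inlet analyzer logs on its own clock; this linearly interpolates
#' the inlet onto the outlet timestamps. Outlet timestamps outside the
#' inlet's range get the nearest inlet value (clipped) and are flagged.
#'
#' @param outlet A [conc_series()].
#' @param inlet A [conc_series()] with at least 2 samples.
#' @return A data.frame with columns `time_s`, `outlet`, `inlet`,
#'   `clipped` (logical).
#' @export
align_pair <- function(outlet, inlet) {
  if (!inherits(outlet, "conc_series") || !inherits(inlet, "conc_series"))
    cf_stop_input("`outlet` and `inlet` must be conc_series")
  if (length(inlet$time_s) < 2L)
    cf_stop_input("`inlet` needs >= 2 samples")
  if (min(outlet$time_s) > max(inlet$time_s) ||
      max(outlet$time_s) < min(inlet$time_s))
    cf_stop("outlet and inlet time ranges are disjoint", "cf_alignment_error")
  vals <- approx(inlet$time_s, inlet$value, xout = outlet$time_s, rule = 2)$y
  clipped <- outlet$time_s < min(inlet$time_s) | outlet$time_s > max(inlet$time_s)
  data.frame(time_s = outlet$time_s, outlet = outlet$value, inlet = vals,
             clipped = clipped)
}
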