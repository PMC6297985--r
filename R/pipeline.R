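# End-to-end pipeline: demultiplex -> background-correct VOC channels
# -> soil-reference-correct CO2/H2O -> flux and gas-exchange rates
# normalized to the (interpolated) leaf area.

#' Pipeline configuration
#'
#' Everything `run_pipeline()` needs besides the raw log and inlet
#' series: cuvette configs, the valve schedule, the psychrometric
#' operating point, which cuvettes serve as empty background and
#' bare-soil reference, and optional per-cuvette leaf-area timelines.
#'
#' @param configs Named list of [cuvette_config()].
#' @param schedule A [valve_schedule()].
#' @param pressure_Pa Operating pressure (default 96000 Pa).
#' @param temperature_K Cuvette air temperature (default 298.15 K).
#' @param background_ids Ids of empty background cuvettes; default: all
#'   cuvettes with role `empty_background`.
#' @param soil_ids Ids of bare-soil reference cuvettes; default: all
#'   cuvettes with role `soil_reference`.
#' @param leaf_area_timelines Optional named list of
#'   [leaf_area_timeline()] per plant cuvette; cuvettes without a
#'   timeline use their static `leaf_area_m2`.
#' @param voc_background_correct Apply empty-cuvette background
#'   correction to VOC channels (default `TRUE`).
#' @param storage_correction Subtract the chamber storage term
#'   (`V dc/dt`, estimated by central differences) from the CO2/H2O
#'   mass balance so diurnal assimilation/transpiration are not lagged
#'   by the cuvette's low-pass response (default `TRUE`).
#' @param smooth_window Derivative smoothing window for
#'   [dynamic_emission()] (default 0).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(configs, schedule, pressure_Pa = 96000,
                            temperature_K = 298.15,
                            background_ids = NULL, soil_ids = NULL,
                            leaf_area_timelines = NULL,
                            voc_background_correct = TRUE,
                            storage_correction = TRUE,
                            smooth_window = 0L) {
  if (!length(configs) || !all(vapply(configs, inherits, logical(1), "cuvette_config")))
    cf_stop_validation("`configs` must be a non-empty list of cuvette_config")
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, `[[`, character(1), "cuvette_id")
  if (!inherits(schedule, "valve_schedule"))
    cf_stop_validation("`schedule` must be a valve_schedule")
  roles <- vapply(configs, `[[`, character(1), "role")
  if (is.null(background_ids))
    background_ids <- names(configs)[roles == "empty_background"]
  if (is.null(soil_ids))
    soil_ids <- names(configs)[roles == "soil_reference"]
  missing_ids <- setdiff(c(background_ids, soil_ids), names(configs))
  if (length(missing_ids))
    cf_stop_validation(sprintf("unknown cuvette id(s): %s",
                               paste(missing_ids, collapse = ", ")))
  bad_bg <- background_ids[roles[background_ids] != "empty_background"]
  if (length(bad_bg))
    cf_stop_validation(sprintf("background id(s) %s do not have role empty_background",
                               paste(bad_bg, collapse = ", ")))
  not_sched <- setdiff(names(configs), schedule$cuvette_order)
  if (length(not_sched))
    cf_stop_validation(sprintf("cuvette(s) %s missing from the valve schedule",
                               paste(not_sched, collapse = ", ")))
  structure(list(configs = configs, schedule = schedule,
                 pressure_Pa = pressure_Pa, temperature_K = temperature_K,
                 background_ids = background_ids, soil_ids = soil_ids,
                 leaf_area_timelines = leaf_area_timelines,
                 voc_background_correct = voc_background_correct,
                 storage_correction = isTRUE(storage_correction),
                 smooth_window = as.integer(smooth_window)),
            class = "pipeline_config")
}

GAS_CHANNELS <- c("co2_ppm", "h2o_molm3")
AUX_CHANNELS <- c("temp_K", "rh")

# leaf area (m2) for a plant cuvette at given timestamps (seconds)
leaf_area_at <- function(pc, cid, time_s) {
  tl <- pc$leaf_area_timelines[[cid]]
  if (is.null(tl)) return(rep_len(pc$configs[[cid]]$leaf_area_m2, length(time_s)))
  interpolate_area(tl, time_s / 86400)
}

inlet_channel_series <- function(inlet, channel) {
  sub <- inlet[inlet$channel == channel, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  conc_series("inlet", channel, sub$time_s, sub$value)
}

#' Run the full processing pipeline
#'
#' Demultiplexes the valve-switched log, subtracts the spline-
#' interpolated empty-cuvette background from every VOC channel,
#' removes the bare-soil contribution from the CO2 and H2O channels,
#' and computes per-cuvette, leaf-area-normalized rates: steady-state
#' and dynamic VOC emission (nmol m-2 s-1), net CO2 assimilation
#' (umol m-2 s-1) and transpiration (mmol m-2 s-1).
#'
#' @param config A [pipeline_config()].
#' @param log Multiplexed log: data.frame or path (see
#'   [read_multiplexed_log()]).
#' @param inlet Inlet analyzer series: data.frame or path; channels
#'   `co2_ppm` and/or `h2o_molm3`. VOC channels are assumed
#'   background-corrected to a zero inlet.
#' @param out_dir Optional output directory; when given, writes
#'   `emission_rates.tsv`, `gas_exchange.tsv` and `run_report.json`.
#' @return List with `emission` (data.frame: cuvette_id, channel,
#'   time_s, leaf_area_m2, emission_ss_nmol_m2_s,
#'   emission_dyn_nmol_m2_s), `gas_exchange` (data.frame: cuvette_id,
#'   time_s, leaf_area_m2, assimilation_umol_m2_s,
#'   transpiration_mmol_m2_s) and `report` (run metadata).
#' @export
run_pipeline <- function(config, log, inlet, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    cf_stop_validation("`config` must be a pipeline_config")
  if (is.character(log)) log <- read_multiplexed_log(log)
  if (is.character(inlet)) inlet <- read_inlet_series(inlet)

  dm <- demultiplex(log, config$schedule)
  channels <- unique(log$channel)
  voc_channels <- setdiff(channels, c(GAS_CHANNELS, AUX_CHANNELS))
  roles <- vapply(config$configs, `[[`, character(1), "role")
  plant_ids <- intersect(names(config$configs)[roles == "plant"],
                         names(dm$series))
  cycle_s <- length(config$schedule$cuvette_order) * config$schedule$dwell_s
  state <- psychrometric_state(config$temperature_K, config$pressure_Pa)

  if (config$voc_background_correct && length(voc_channels) &&
      !length(config$background_ids))
    cf_stop_validation(paste0("VOC background correction requested but no ",
                              "empty_background cuvettes configured"))

  emission <- list(); gasx <- list()
  if (!length(plant_ids))
    warning("no plant cuvettes present: rates tables will be empty",
            call. = FALSE)

  for (cid in plant_ids) {
    cfg <- config$configs[[cid]]
    per_chan <- dm$series[[cid]]
    # --- VOC channels -> emission rates
    for (ch in intersect(voc_channels, names(per_chan))) {
      ser <- per_chan[[ch]]
      if (config$voc_background_correct) {
        bgs <- lapply(intersect(config$background_ids, names(dm$series)),
                      function(b) dm$series[[b]][[ch]])
        bgs <- Filter(Negate(is.null), bgs)
        if (!length(bgs))
          cf_stop_validation(sprintf("no background series available for channel %s", ch))
        ser <- background_correct(ser, bgs, cycle_s = cycle_s)
      }
      A <- leaf_area_at(config, cid, ser$time_s)
      ss <- lpm_to_m3s(cfg$inlet_flow_lpm) / A * ser$value
      dyn <- if (length(ser$time_s) >= 3L) {
        # constant-leaf-area inversion, then rescale to A(t)
        d <- dynamic_emission(ser, 0, cfg, smooth_window = config$smooth_window)
        d$value * cfg$leaf_area_m2 / A
      } else ss
      emission[[length(emission) + 1L]] <- data.frame(
        cuvette_id = cid, channel = ch, time_s = ser$time_s,
        leaf_area_m2 = A, emission_ss_nmol_m2_s = ss,
        emission_dyn_nmol_m2_s = dyn)
    }
    # --- CO2 / H2O -> assimilation and transpiration
    co2 <- per_chan[["co2_ppm"]]; h2o <- per_chan[["h2o_molm3"]]
    if (!is.null(co2) || !is.null(h2o)) {
      soil_series <- function(ch) {
        ss <- lapply(intersect(config$soil_ids, names(dm$series)),
                     function(s) dm$series[[s]][[ch]])
        Filter(Negate(is.null), ss)
      }
      gx <- NULL
      if (!is.null(co2)) {
        in_co2 <- inlet_channel_series(inlet, "co2_ppm")
        if (is.null(in_co2))
          cf_stop_validation("inlet series lacks channel co2_ppm")
        co2_corr <- co2
        soils <- soil_series("co2_ppm")
        if (length(soils)) {
          pooled <- pool_series(soils)
          soil_at <- spline_interp_held(pooled$time_s, pooled$value, co2$time_s)
          in_at <- align_onto(in_co2, co2$time_s, "inlet")
          co2_corr <- conc_series(cid, "co2_ppm", co2$time_s,
                                  co2$value - (soil_at - in_at))
        }
        pair <- align_pair(co2_corr, in_co2)
        A <- leaf_area_at(config, cid, pair$time_s)
        assim <- net_co2_assimilation(pair$inlet, pair$outlet,
                                      cfg$inlet_flow_lpm, 1, state) / A
        if (config$storage_correction && length(pair$time_s) >= 3L) {
          # subtract the chamber storage term n_air * dx/dt (the cuvette
          # is a low-pass filter; without this the diurnal signal lags)
          n_air <- config$pressure_Pa * l_to_m3(cfg$volume_l) /
            (R_GAS * config$temperature_K)
          dxdt <- grid_derivative(pair$time_s, pair$outlet)
          assim <- assim - n_air * dxdt / A
        }
        gx <- data.frame(cuvette_id = cid, time_s = pair$time_s,
                         leaf_area_m2 = A, assimilation_umol_m2_s = assim)
      }
      if (!is.null(h2o)) {
        in_h2o <- inlet_channel_series(inlet, "h2o_molm3")
        if (is.null(in_h2o))
          cf_stop_validation("inlet series lacks channel h2o_molm3")
        h2o_corr <- h2o
        soils <- soil_series("h2o_molm3")
        if (length(soils)) {
          pooled <- pool_series(soils)
          soil_at <- spline_interp_held(pooled$time_s, pooled$value, h2o$time_s)
          in_at <- align_onto(in_h2o, h2o$time_s, "inlet")
          h2o_corr <- conc_series(cid, "h2o_molm3", h2o$time_s,
                                  h2o$value - (soil_at - in_at))
        }
        pair <- align_pair(h2o_corr, in_h2o)
        A <- leaf_area_at(config, cid, pair$time_s)
        tr <- transpiration_rate(pair$inlet, pair$outlet,
                                 cfg$inlet_flow_lpm, 1) / A
        if (config$storage_correction && length(pair$time_s) >= 3L) {
          dhdt <- grid_derivative(pair$time_s, pair$outlet)
          tr <- tr + l_to_m3(cfg$volume_l) * dhdt / A * 1e3
        }
        tr_df <- data.frame(cuvette_id = cid, time_s = pair$time_s,
                            leaf_area_m2 = A, transpiration_mmol_m2_s = tr)
        gx <- if (is.null(gx)) tr_df else
          merge(gx, tr_df, by = c("cuvette_id", "time_s", "leaf_area_m2"),
                all = TRUE)
      }
      if (!is.null(gx)) gasx[[length(gasx) + 1L]] <- gx
    }
  }

  empty_emission <- data.frame(cuvette_id = character(), channel = character(),
                               time_s = numeric(), leaf_area_m2 = numeric(),
                               emission_ss_nmol_m2_s = numeric(),
                               emission_dyn_nmol_m2_s = numeric())
  empty_gasx <- data.frame(cuvette_id = character(), time_s = numeric(),
                           leaf_area_m2 = numeric(),
                           assimilation_umol_m2_s = numeric(),
                           transpiration_mmol_m2_s = numeric())
  emission_df <- if (length(emission)) do.call(rbind, emission) else empty_emission
  gasx_df <- if (length(gasx)) do.call(rbind, gasx) else empty_gasx
  emission_df <- emission_df[order(emission_df$cuvette_id, emission_df$channel,
                                   emission_df$time_s), , drop = FALSE]
  gasx_df <- gasx_df[order(gasx_df$cuvette_id, gasx_df$time_s), , drop = FALSE]
  rownames(emission_df) <- NULL; rownames(gasx_df) <- NULL

  report <- list(
    package_version = as.character(utils::packageVersion("cuvetteflux")),
    n_records = nrow(log), kept = dm$kept, discarded = dm$discarded,
    counts_per_channel = dm$counts,
    channels = channels, voc_channels = voc_channels,
    plant_cuvettes = plant_ids,
    background_ids = config$background_ids, soil_ids = config$soil_ids,
    schedule = unclass(config$schedule),
    pressure_Pa = config$pressure_Pa, temperature_K = config$temperature_K
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(emission_df, file.path(out_dir, "emission_rates.tsv"),
                       sep = "\t")
    data.table::fwrite(gasx_df, file.path(out_dir, "gas_exchange.tsv"),
                       sep = "\t")
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  }

  list(emission = emission_df, gas_exchange = gasx_df, report = report)
}
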