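# Delimited-text file formats: multiplexed logs, inlet series,
# per-cuvette concentration series, cuvette config tables, pipeline
# configuration (JSON) and run manifests.

#' Read / write a multiplexed sensor log
#'
#' Tab-separated text with header columns `time_s`, `active_cuvette`,
#' `channel`, `value`.
#'
#' @param path File path.
#' @return `read_multiplexed_log()`: a data.frame.
#' @export
read_multiplexed_log <- function(path) {
  if (!file.exists(path))
    cf_stop_validation(sprintf("log file not found: %s", path))
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("time_s", "channel", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cf_stop_validation(sprintf("%s: missing column(s) %s", path,
                               paste(miss, collapse = ", ")))
  df
}

#' @param log Data.frame to write.
#' @rdname read_multiplexed_log
#' @export
write_multiplexed_log <- function(log, path) {
  data.table::fwrite(log, path, sep = "\t")
  invisible(path)
}

#' Read / write an inlet analyzer series
#'
#' Tab-separated text with columns `time_s`, `channel`, `value`.
#'
#' @param path File path.
#' @return `read_inlet_series()`: a data.frame.
#' @export
read_inlet_series <- function(path) {
  if (!file.exists(path))
    cf_stop_validation(sprintf("inlet file not found: %s", path))
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  miss <- setdiff(c("time_s", "channel", "value"), names(df))
  if (length(miss))
    cf_stop_validation(sprintf("%s: missing column(s) %s", path,
                               paste(miss, collapse = ", ")))
  df
}

#' @param inlet Data.frame to write.
#' @rdname read_inlet_series
#' @export
write_inlet_series <- function(inlet, path) {
  data.table::fwrite(inlet, path, sep = "\t")
  invisible(path)
}

#' Read / write per-cuvette concentration series
#'
#' Tab-separated text with columns `cuvette_id`, `compound_id`,
#' `time_s`, `value`.
#'
#' @param path File path.
#' @return `read_conc_series()`: a list of [conc_series()] (one per
#'   cuvette/compound pair found in the file).
#' @export
read_conc_series <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  miss <- setdiff(c("cuvette_id", "compound_id", "time_s", "value"), names(df))
  if (length(miss))
    cf_stop_validation(sprintf("%s: missing column(s) %s", path,
                               paste(miss, collapse = ", ")))
  parts <- split(df, list(df$cuvette_id, df$compound_id), drop = TRUE)
  lapply(parts, function(p)
    conc_series(p$cuvette_id[1], p$compound_id[1], p$time_s, p$value))
}

#' @param series A [conc_series()] or list of them.
#' @rdname read_conc_series
#' @export
write_conc_series <- function(series, path) {
  if (inherits(series, "conc_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read / write a cuvette configuration table
#'
#' Flat per-cuvette key-value table as tab-separated text with columns
#' `cuvette_id`, `volume_l`, `inlet_flow_lpm`, `role`, `leaf_area_m2`.
#'
#' @param path File path.
#' @return `read_cuvette_configs()`: named list of [cuvette_config()].
#' @export
read_cuvette_configs <- function(path) {
  if (!file.exists(path))
    cf_stop_validation(sprintf("cuvette config file not found: %s", path))
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("cuvette_id", "volume_l", "inlet_flow_lpm", "role", "leaf_area_m2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cf_stop_validation(sprintf("%s: missing column(s) %s", path,
                               paste(miss, collapse = ", ")))
  configs <- lapply(seq_len(nrow(df)), function(i)
    cuvette_config(df$cuvette_id[i], df$volume_l[i], df$inlet_flow_lpm[i],
                   df$role[i], df$leaf_area_m2[i]))
  names(configs) <- df$cuvette_id
  configs
}

#' @param configs Named list of [cuvette_config()] to write.
#' @rdname read_cuvette_configs
#' @export
write_cuvette_configs <- function(configs, path) {
  df <- do.call(rbind, lapply(configs, function(cf)
    data.frame(cuvette_id = cf$cuvette_id, volume_l = cf$volume_l,
               inlet_flow_lpm = cf$inlet_flow_lpm, role = cf$role,
               leaf_area_m2 = cf$leaf_area_m2)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
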