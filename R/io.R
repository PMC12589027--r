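#' Read and write spike trains as TSV
#'
#' Spike trains are exchanged as tab-separated text with a header line and
#' the two columns `time_s` and `unit_id` - the natural reduction of both
#' simulations and multielectrode-array recordings after spike detection.
#' Rows need not be sorted on disk; trains are canonicalized (sorted by
#' time, then unit) on load. Unit class flags, when available, travel in an
#' optional JSON sidecar `<path>.meta.json`.
#'
#' @param path file path
#' @param spikes a [spike_train()]
#' @param write_meta also write the `is_exc` sidecar when flags are present
#' @return `read_spikes()` returns a [spike_train()]; `write_spikes()`
#'   returns `path` invisibly
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty spike file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[1:2], c("time_s", "unit_id")))
    stop("expected header 'time_s<TAB>unit_id' in ", path)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  time_s <- numeric(n)
  unit <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("line ", i + 1L, ": expected 2 tab-separated fields")
    tv <- suppressWarnings(as.numeric(f[1L]))
    uv <- suppressWarnings(as.integer(f[2L]))
    if (is.na(tv)) stop("line ", i + 1L, ": non-numeric time field '",
                        f[1L], "'")
    if (is.na(uv) || uv < 1L)
      stop("line ", i + 1L, ": invalid unit id '", f[2L], "'")
    if (tv < 0) stop("line ", i + 1L, ": negative spike time")
    time_s[i] <- tv
    unit[i] <- uv
  }
  is_exc <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$is_exc)) is_exc <- as.logical(meta$is_exc)
  }
  spike_train(time_s, unit, is_exc = is_exc)
}

#' @rdname read_spikes
#' @export
write_spikes <- function(spikes, path, write_meta = TRUE) {
  stopifnot(inherits(spikes, "spike_train"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s\tunit_id", con)
  if (nrow(spikes) > 0)
    writeLines(sprintf("%.10g\t%d", spikes$time_s, spikes$unit), con)
  is_exc <- attr(spikes, "is_exc")
  if (write_meta && !is.null(is_exc)) {
    jsonlite::write_json(list(format = "snncrit-spikes", version = 1L,
                              is_exc = is_exc),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON configuration (or takes an equivalent named list) with the
#' optional top-level sections `neuron`, `stdp` and `protocol`; any field
#' that is missing takes the package default, so an empty configuration is
#' the full reference parameter set. A `preset` field inside `stdp` (one of
#' `"crt"`, `"sub"`, `"sup"`) selects the named depression/potentiation
#' balance; explicit `beta_E`/`beta_I` values win over the preset. All
#' parameter constraints (including the inhibitory-window validity
#' condition `tau_I1/tau_I2 < min(1/beta_I, 1)`) are enforced and violations
#' are reported with the offending field.
#'
#' @param config a file path to a JSON document, or a named list
#' @return a list with validated `neuron` ([neuron_params()]), `stdp`
#'   ([stdp_params()]) and `protocol` (named list) sections
#' @export
#' @examples
#' cfg <- load_config(list(stdp = list(preset = "crt")))
#' cfg$stdp$beta_I  # 1.15
load_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  neuron <- do.call(neuron_params, as.list(config$neuron))
  stdp_args <- as.list(config$stdp)
  if (!is.null(stdp_args$preset)) {
    preset <- match.arg(stdp_args$preset, names(stdp_presets))
    defaults <- stdp_presets[[preset]]
    if (is.null(stdp_args$beta_E)) stdp_args$beta_E <- defaults[["beta_E"]]
    if (is.null(stdp_args$beta_I)) stdp_args$beta_I <- defaults[["beta_I"]]
    stdp_args$preset <- NULL
  }
  stdp <- do.call(stdp_params, stdp_args)
  protocol <- utils::modifyList(
    list(n_exc = 80L, n_inh = 20L, develop_s = 72 * 3600,
         n_patterns = 4L, pattern_size = 6L, amplitude = 30,
         stimuli_per_pattern = 900L, stim_rate_hz = 1,
         spontaneous_s = 12 * 3600, monitor_every_s = 3600, monitor_s = 600,
         n_trials = 40L, pre_run_s = 10, window_s = 1, seed = 1L),
    as.list(config$protocol))
  list(neuron = neuron, stdp = stdp, protocol = protocol)
}

#' Save or restore a checkpointed network state
#'
#' Serializes the complete mutable simulation state - membrane potentials,
#' conductances, resources, weight matrix, refractory timers, plasticity
#' traces, the delayed-event buffers, the random-stream words, and the clock
#' - as a single JSON document, so a run can be stopped and continued with
#' bit-identical results. JSON (not a binary container) keeps checkpoints
#' diffable and environment-independent.
#'
#' @param state a network state
#' @param path file path
#' @return `load_state()` returns the restored `network_state`;
#'   `save_state()` returns `path` invisibly
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "network_state"))
  doc <- list(
    format = "snncrit-state", version = 1L,
    t = state$t, n = state$n, is_exc = state$is_exc,
    v = state$v, g_exc = state$g_exc, g_inh = state$g_inh, x = state$x,
    w = as.vector(state$w), refrac_until = state$refrac_until,
    tr_e = state$tr_e, tr_i1 = state$tr_i1, tr_i2 = state$tr_i2,
    pend_exc = as.vector(state$pend_exc), pend_inh = as.vector(state$pend_inh),
    pend_rows = nrow(state$pend_exc),
    rng = state$rng,
    params = unclass(state$params), stdp = unclass(state$stdp))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "snncrit-state"))
    stop("not a snncrit state checkpoint: ", path)
  n <- as.integer(doc$n)
  rows <- as.integer(doc$pend_rows)
  # refractory timers may have serialized -Inf as NA
  refrac <- as.numeric(doc$refrac_until)
  refrac[is.na(refrac)] <- -Inf
  state <- list(
    t = doc$t, n = n, is_exc = as.logical(doc$is_exc),
    v = as.numeric(doc$v), g_exc = as.numeric(doc$g_exc),
    g_inh = as.numeric(doc$g_inh), x = as.numeric(doc$x),
    w = matrix(as.numeric(doc$w), n, n),
    refrac_until = refrac,
    tr_e = as.numeric(doc$tr_e), tr_i1 = as.numeric(doc$tr_i1),
    tr_i2 = as.numeric(doc$tr_i2),
    pend_exc = matrix(as.numeric(doc$pend_exc), rows, n),
    pend_inh = matrix(as.numeric(doc$pend_inh), rows, n),
    rng = as.integer(doc$rng),
    # JSON stores whole numbers as integers; parameters are doubles
    params = do.call(neuron_params, lapply(as.list(doc$params), as.numeric)),
    stdp = do.call(stdp_params, lapply(as.list(doc$stdp), as.numeric)))
  class(state) <- "network_state"
  state
}

#' Run manifest
#'
#' Records everything needed to regenerate a result: the configuration
#' snapshot, the named seeds, the package version, per-stage output paths
#' and a timestamp. `write_manifest()` additionally verifies that every
#' listed output file exists.
#'
#' @param config a configuration as accepted by [load_config()]
#' @param seeds named list/vector of every seed used
#' @param outputs named list of output file paths
#' @param path file path for the JSON manifest
#' @return `run_manifest()` returns the manifest list; `write_manifest()`
#'   returns `path` invisibly
#' @export
run_manifest <- function(config, seeds, outputs = list()) {
  list(format = "snncrit-manifest", version = 1L,
       package_version = as.character(utils::packageVersion("snncrit")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config, seeds = seeds, outputs = outputs)
}

#' @rdname run_manifest
#' @export
write_manifest <- function(config, seeds, outputs, path) {
  missing <- unlist(outputs)[!file.exists(unlist(outputs))]
  if (length(missing) > 0)
    stop("manifest lists missing output files: ",
         paste(missing, collapse = ", "))
  jsonlite::write_json(run_manifest(config, seeds, outputs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
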