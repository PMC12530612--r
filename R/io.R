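#' Derive labeled per-stage seeds from a master seed
#'
#' Deterministic, collision-resistant mapping from (master seed, label) to a
#' 31-bit seed, so each pipeline stage gets its own reproducible stream and
#' relabeling one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param labels character vector of unique stage labels.
#' @return integer seed(s), one per label, in \code{[1, 2^31 - 2]}.
#' @export
derive_seeds <- function(master, labels) {
  if (anyDuplicated(labels))
    stop("stage labels must be unique", call. = FALSE)
  M <- 2147483647  # 2^31 - 1, prime
  vapply(labels, function(lab) {
    h <- as.numeric(master) %% M
    for (code in utf8ToInt(lab)) h <- (h * 31 + code) %% M
    as.integer(h %% (M - 1) + 1)
  }, integer(1), USE.NAMES = length(labels) > 1)
}

#' Load an experiment configuration from JSON
#'
#' Reads a JSON file whose (all optional) top-level blocks \code{neuron},
#' \code{synapse}, \code{network}, \code{protocol}, \code{analysis} and
#' \code{seeds} mirror the parameter constructors field-for-field, merges
#' them over the package defaults, and validates everything at once.  The
#' schema has a named slot for every model constant, so values transcribed
#' from a parameter table drop in directly.  Unknown keys produce a
#' warning, not an error; an empty file yields the all-defaults
#' configuration.
#'
#' @param path JSON file path.
#' @return an object of class \code{"experiment_config"}: list with
#'   \code{neuron}, \code{synapse}, \code{network} (constructed objects),
#'   \code{protocol}, \code{analysis}, \code{seeds} (lists of values), and
#'   \code{provenance} (which top-level blocks came from the file).
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path) && file.size(path) > 0)
    jsonlite::read_json(path, simplifyVector = TRUE) else list()
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  known <- c("neuron", "synapse", "network", "protocol", "analysis", "seeds")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config blocks: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  errs <- character()
  build <- function(ctor, block, name) {
    args <- raw[[block]]
    if (!is.null(args)) {
      bad <- setdiff(names(args), names(formals(ctor)))
      if (length(bad)) {
        warning(sprintf("ignoring unknown %s keys: %s", block,
                        paste(bad, collapse = ", ")), call. = FALSE)
        args <- args[setdiff(names(args), bad)]
      }
    }
    tryCatch(do.call(ctor, .as_plain_args(args)),
             error = function(e) {
               errs <<- c(errs, sprintf("%s: %s", block, conditionMessage(e)))
               NULL
             })
  }
  neuron <- build(neuron_params, "neuron")
  synapse <- build(synapse_params, "synapse")
  network <- build(connectivity_config, "network")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  protocol <- utils::modifyList(
    list(condition = "center_only", n_trials = 20, surround_rate = 300),
    .as_plain_args(raw$protocol))
  analysis <- utils::modifyList(
    list(threshold = 0.2, reversal_e = -10, reversal_i = -75,
         junction = -10, delta_t = 20),
    .as_plain_args(raw$analysis))
  seeds <- utils::modifyList(list(master = 1L), .as_plain_args(raw$seeds))
  structure(list(neuron = neuron, synapse = synapse, network = network,
                 protocol = protocol, analysis = analysis, seeds = seeds,
                 provenance = intersect(names(raw), known)),
            class = "experiment_config")
}

.as_plain_args <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)
}

#' Save a resolved experiment configuration as JSON
#'
#' Writes the fully resolved (defaults merged) configuration, suitable for
#' placing next to outputs so a run can be repeated bit-identically.
#'
#' @param cfg an \code{"experiment_config"}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  out <- list(neuron = unclass(cfg$neuron),
              synapse = lapply(unclass(cfg$synapse), function(v)
                if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
              network = unclass(cfg$network)[
                c("grid_side", "sigma_E", "sigma_I", "p", "torus")],
              protocol = cfg$protocol, analysis = cfg$analysis,
              seeds = cfg$seeds)
  out$network$p <- as.list(out$network$p)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write clamp traces as columnar text
#'
#' Sweep-averaged currents, one column per holding potential
#' (\code{I_<V>mV_pA}) next to \code{time_ms}, plus a JSON sidecar with the
#' holding potentials, junction potential and optional generator
#' configuration / ground truth.
#'
#' @param cts a \code{\link{clamp_trace_set}}.
#' @param file output path for the tab-separated table; the sidecar is
#'   written to \code{<file>.json}.
#' @param truth optional \code{\link{ground_truth_conductance}} stored in
#'   the sidecar.
#' @return \code{file}, invisibly.
#' @export
write_clamp_traces <- function(cts, file, truth = NULL) {
  stopifnot(inherits(cts, "clamp_trace_set"))
  df <- data.frame(time_ms = cts$time)
  for (k in seq_along(cts$holding))
    df[[sprintf("I_%gmV_pA", cts$holding[k])]] <- rowMeans(cts$traces[[k]])
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(holding_mV = cts$holding, junction_mV = cts$junction,
               corrected = cts$corrected)
  if (!is.null(truth))
    side$ground_truth <- list(ge_nS = truth$ge, gi_nS = truth$gi,
                              description = truth$description)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read clamp traces written by \code{\link{write_clamp_traces}}
#'
#' @param file path of the columnar table (with \code{<file>.json} sidecar).
#' @return a \code{\link{clamp_trace_set}} (single sweep-averaged sweep per
#'   potential).
#' @export
read_clamp_traces <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  traces <- lapply(seq_along(side$holding_mV), function(k) df[[k + 1]])
  clamp_trace_set(df$time_ms, traces, side$holding_mV, side$junction_mV,
                  corrected = isTRUE(side$corrected))
}

#' Write a zone map as CSV
#'
#' Long-format CSV with \code{row}, \code{col}, \code{amplitude_pA} (and
#' the normalized value and center flag when masks exist).
#'
#' @param zm a \code{\link{zone_map}} or plain amplitude matrix.
#' @param file output CSV path.
#' @return \code{file}, invisibly.
#' @export
write_zone_map <- function(zm, file) {
  if (!inherits(zm, "zone_map")) zm <- zone_map(zm)
  nr <- nrow(zm$amplitudes); nc <- ncol(zm$amplitudes)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  df <- data.frame(grid,
                   amplitude_pA = zm$amplitudes[cbind(grid$row, grid$col)],
                   normalized = zm$normalized[cbind(grid$row, grid$col)],
                   center = zm$center_mask[cbind(grid$row, grid$col)])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a zone map CSV written by \code{\link{write_zone_map}}
#'
#' @param file CSV path.
#' @param ... passed to \code{\link{zone_map}} (cell size, soma, threshold).
#' @return a \code{\link{zone_map}}.
#' @export
read_zone_map <- function(file, ...) {
  df <- utils::read.csv(file)
  amp <- matrix(NA_real_, max(df$row), max(df$col))
  amp[cbind(df$row, df$col)] <- df$amplitude_pA
  zone_map(amp, ...)
}

#' Write a spike raster as columnar text
#'
#' @param recording a \code{"trial_recording"}.
#' @param file output path (tab-separated: population, neuron_id, time_ms).
#' @return \code{file}, invisibly.
#' @export
write_raster <- function(recording, file) {
  stopifnot(inherits(recording, "trial_recording"))
  df <- data.frame(population = recording$spikes$pop,
                   neuron_id = recording$spikes$id,
                   time_ms = recording$spikes$time)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
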