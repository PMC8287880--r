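# configuration, serialization and run manifests

config_param_keys <- c("v0", "v", "K", "n", "k_deg", "k_B", "k_D", "k_C")
config_top_keys <- c(config_param_keys, "parameters", "variant",
                     "variant.kind", "variant.magnitude", "protocol",
                     "experiment", "output_dir", "seed", "log_level")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (dialect chosen by extension)
#' describing circuit parameters, variant, stress protocol and experiment
#' settings. Parameters may be given either flat (keys named exactly `v0`,
#' `v`, `K`, `n`, `k_deg`, `k_B`, `k_D`, `k_C`, `variant.kind`,
#' `variant.magnitude`) or nested under `parameters:` / `variant:`. Missing
#' parameters default to the published wild-type set; unknown keys are
#' rejected, and validation errors name the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `"run_config"` with elements `params`
#'   ([circuit_params()]), `variant` ([circuit_variant()]), `protocol`,
#'   `experiment`, `output_dir`, `seed`, `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_top_keys)
  if (length(unknown) > 0)
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))

  pvals <- raw$parameters %||% list()
  bad <- setdiff(names(pvals), config_param_keys)
  if (length(bad) > 0)
    abort(paste0("unknown parameter key(s): ", paste(bad, collapse = ", ")))
  for (k in config_param_keys)
    if (!is.null(raw[[k]])) pvals[[k]] <- raw[[k]]
  params <- tryCatch(do.call(circuit_params, pvals),
                     error = function(e)
                       abort(paste0("invalid parameters: ",
                                    conditionMessage(e))))

  vr <- raw$variant %||% list()
  if (is.character(vr)) vr <- list(kind = vr)
  if (!is.null(raw[["variant.kind"]])) vr$kind <- raw[["variant.kind"]]
  if (!is.null(raw[["variant.magnitude"]]))
    vr$magnitude <- raw[["variant.magnitude"]]
  variant <- circuit_variant(vr$kind %||% "wild_type", vr$magnitude)

  protocol <- parse_protocol(raw$protocol)
  structure(list(params = params, variant = variant, protocol = protocol,
                 experiment = raw$experiment %||% list(),
                 output_dir = raw$output_dir %||% ".",
                 seed = as.integer(raw$seed %||% 1L),
                 log_level = raw$log_level %||% "info"),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_protocol <- function(p) {
  if (is.null(p)) return(step_protocol(500, 1, 2000))
  type <- p$type %||% "step"
  switch(type,
    step = step_protocol(p$t_on %||% 500, p$L %||% 1,
                         p$duration %||% 2000),
    memory = memory_protocol(p$t_on %||% 500, p$t_off %||% 1500,
                             p$gap %||% 800, p$L %||% 1,
                             p$post_duration %||% 1000),
    constant = constant_protocol(p$L %||% 0, p$duration %||% 1000),
    abort(paste0("unknown protocol type: ", type))
  )
}

#' Save a run configuration
#'
#' Writes a [load_config()] object back to YAML or JSON so that a
#' save-then-load round trip reproduces the configuration.
#'
#' @param config A `run_config` object.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  prot <- config$protocol
  segs <- protocol_segments(prot)
  ptype <- if (nrow(segs) >= 4) "memory"
           else if (nrow(segs) == 1) "constant" else "step"
  plist <- switch(ptype,
    step = list(type = "step", t_on = segs$start[2], L = segs$L[2],
                duration = protocol_duration(prot)),
    constant = list(type = "constant", L = segs$L[1],
                    duration = protocol_duration(prot)),
    memory = list(type = "memory", t_on = segs$start[2],
                  t_off = segs$start[3], gap = segs$start[4] - segs$start[3],
                  L = segs$L[2],
                  post_duration = protocol_duration(prot) - segs$start[4]))
  out <- list(parameters = unclass(config$params),
              variant = list(kind = config$variant$kind),
              protocol = plist,
              experiment = config$experiment,
              output_dir = config$output_dir,
              seed = config$seed, log_level = config$log_level)
  if (!is.null(config$variant$magnitude))
    out$variant$magnitude <- config$variant$magnitude
  if (length(out$experiment) == 0) out$experiment <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(out, path)
  invisible(path)
}

#' Write and read tidy trace / trajectory tables
#'
#' Trajectories, ensembles and synthetic traces are exchanged as tidy
#' long-format CSV (one row per cell and frame). Large ensembles can
#' alternatively be written to Apache Arrow parquet, a compact binary
#' columnar container.
#'
#' @param data A trajectory, ensemble, or trace tibble.
#' @param path Destination path (`.csv` or `.parquet`).
#' @return `path`, invisibly (`write_traces()`); a tibble (`read_traces()`).
#' @export
write_traces <- function(data, path) {
  df <- as.data.frame(data)
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the 'arrow' package is required for parquet output")
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the 'arrow' package is required for parquet input")
    as_tibble(arrow::read_parquet(path))
  } else {
    as_tibble(utils::read.csv(path))
  }
}

# JSON run manifest: everything needed to reproduce the artifacts
write_manifest <- function(dir, config, outputs, extra = list()) {
  cfg_file <- file.path(dir, "config.snapshot.yaml")
  save_config(config, cfg_file)
  manifest <- c(list(
    package = "sigvcircuit",
    version = as.character(utils::packageVersion("sigvcircuit")),
    schema_version = "1",
    seed = config$seed,
    config_hash = rlang::hash(readLines(cfg_file)),
    outputs = basename(outputs),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}
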