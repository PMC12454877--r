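# Configuration, serialization and provenance glue: schema-validated YAML/JSON
# configs, trace CSV round-trips, feature batch tables, and run manifests.
# The `trnlab` command-line entry point (inst/cli/trnlab.R) is a thin wrapper
# over these exported functions.

config_schema <- function() {
  list(
    model = list(type = "Spp1", temperature = 25, reduced = TRUE,
                 params = list()),
    protocol = list(name = "burst", steady_v = -65, window = 14000,
                    dt = 0.025, amplitude = 0.15),
    network = list(n_trn = 40, n_tc = 80,
                   composition = list(ecel1 = 1, spp1 = 0, runaway = 0),
                   ct = list(), seed = 1))
}

validate_node <- function(value, default, path) {
  if (!is.list(default)) return(value)
  unknown <- setdiff(names(value), names(default))
  if (length(unknown) > 0) {
    stop_config(paste0("unknown configuration key(s) under '", path, "': ",
                       paste(unknown, collapse = ", ")))
  }
  out <- default
  for (nm in names(value)) {
    # free-form leaves (empty-list defaults) accept any content
    if (is.list(default[[nm]]) && length(default[[nm]]) == 0) {
      out[[nm]] <- value[[nm]]
    } else {
      out[[nm]] <- validate_node(value[[nm]], default[[nm]],
                                 paste0(path, "/", nm))
    }
  }
  out
}

#' Load and validate a configuration file
#'
#' Reads YAML or JSON, rejects unknown keys, and fills defaults. Top-level
#' sections: `model`, `protocol`, `network`.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config(paste("no such config file:", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  validate_node(raw, config_schema(), "")
}

#' Save a configuration file
#'
#' @param config configuration list.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' Write a voltage trace to CSV
#'
#' Columns `t_ms`, `v_mV`, `i_nA`; protocol metadata goes to a JSON sidecar
#' (`<path>.json`).
#'
#' @param trace a `trn_trace`.
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  df <- data.frame(t_ms = trace$t, v_mV = trace$v, i_nA = trace$i_inj)
  write.csv(format(df, digits = 9, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    md <- attr(trace, "metadata")
    md$dt <- attr(trace, "dt")
    md$ground_truth <- NULL
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a voltage trace from CSV
#'
#' @param path CSV path written by [write_trace_csv()].
#' @return a `trn_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("t_ms", "v_mV") %in% names(df))) {
    stop_format("trace CSV needs t_ms and v_mV columns")
  }
  md <- list(protocol = "file")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    md <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  dt <- md$dt %||% (if (nrow(df) > 1) df$t_ms[2] - df$t_ms[1] else NA_real_)
  md$dt <- NULL
  new_trace(tibble::tibble(t = df$t_ms, v = df$v_mV,
                           i_inj = df$i_nA %||% 0),
            dt = dt, metadata = md)
}

#' Batch feature extraction
#'
#' Extracts the feature vector of every trace CSV in a directory into one
#' tidy table.
#'
#' @param dir directory of trace CSVs.
#' @param pattern file pattern (default `\\.csv$`).
#' @return tibble with `file` plus feature columns.
#' @export
batch_features <- function(dir, pattern = "\\.csv$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  purrr::map_dfr(files, function(f) {
    fv <- extract_features(read_trace_csv(f))
    fv$etype <- classify_etype(fv)
    dplyr::bind_cols(tibble::tibble(file = basename(f)), fv)
  })
}

#' Write a run manifest
#'
#' Records command, seed(s), package version, timestamp, and output paths as
#' JSON next to the outputs.
#'
#' @param path manifest path.
#' @param command command name.
#' @param seed seed(s) used.
#' @param outputs character vector of output paths.
#' @param extra optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA, outputs = character(0),
                           extra = list()) {
  manifest <- c(list(command = command, seed = seed,
                     package = "trnlab",
                     version = as.character(utils::packageVersion("trnlab")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     outputs = outputs),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
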