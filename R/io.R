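#' Load model constants from a YAML config file
#'
#' Reads a YAML file whose keys override individual [esa_constants()]
#' fields; an empty file yields the pure defaults (target 11-12 g/dL, mean
#' lifespan 61.2 d, half-lives 24/48/138 h, ...). Unknown keys are rejected
#' with their key path.
#'
#' @param path Path to a YAML file.
#' @return A validated `esa_constants` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop("config error: top level must be a mapping in ", path, call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(formals(esa_constants)))
  if (length(unknown) > 0) {
    stop("config error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(esa_constants, cfg)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write and read session logs as CSV
#'
#' The log holds one row per week (`week`, `phase`, `visible`, `true_hb`,
#' `observed_hb`, `dose`, `bleed_fraction`, `rbc_lifespan`); seeds, arm and
#' patient parameters travel in `#`-comment header lines so a log file is
#' self-describing. Numeric fields are written with full precision, so a
#' write-then-read round trip reproduces every field exactly.
#'
#' @param record An `esa_session` from [run_session()].
#' @param path Output / input file path.
#' @return `write_session_csv()` returns `path` invisibly;
#'   `read_session_csv()` returns an `esa_session` data frame with the
#'   patient and config reattached (the final engine state is not
#'   serialised).
#' @export
write_session_csv <- function(record, path) {
  stopifnot(inherits(record, "data.frame"))
  cfg <- attr(record, "config")
  pat <- attr(record, "patient")
  hdr <- c(
    "# eposim session log",
    sprintf("# eposim_version: %s", as.character(utils::packageVersion("eposim"))),
    sprintf("# half_life: %.17g", cfg$half_life),
    sprintf("# interval: %s", cfg$interval),
    sprintf("# mode: %s", cfg$mode),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# patient_seed: %d", pat$seed),
    sprintf("# starting_hb: %.17g", pat$starting_hb),
    sprintf("# sensitivity: %.17g", pat$sensitivity),
    sprintf("# baseline_production: %.17g", pat$baseline_production)
  )
  num_cols <- c("true_hb", "observed_hb", "dose", "bleed_fraction", "rbc_lifespan")
  out <- as.data.frame(record)[, c("week", "phase", "visible", num_cols)]
  for (cc in num_cols) out[[cc]] <- fmt_num(out[[cc]])
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @param constants Constants to attach when reading (the CSV stores the
#'   arm and patient, not the full constant set); defaults to
#'   [esa_constants()].
#' @export
read_session_csv <- function(path, constants = esa_constants()) {
  if (!file.exists(path)) {
    stop("parse error: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^# ([A-Za-z_]+): (.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  rec <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  need <- c("week", "phase", "visible", "true_hb", "observed_hb",
            "dose", "bleed_fraction", "rbc_lifespan")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0) {
    stop("parse error in ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cc in c("true_hb", "observed_hb", "dose", "bleed_fraction", "rbc_lifespan")) {
    rec[[cc]] <- as.numeric(rec[[cc]])
  }
  rec$week <- as.integer(rec$week)
  rec$visible <- as.logical(rec$visible)
  patient <- structure(
    list(starting_hb = as.numeric(meta$starting_hb),
         sensitivity = as.numeric(meta$sensitivity),
         baseline_production = as.numeric(meta$baseline_production),
         seed = as.integer(meta$patient_seed)),
    class = "esa_patient"
  )
  config <- session_config(half_life = as.numeric(meta$half_life),
                           interval = meta$interval, mode = meta$mode,
                           seed = as.integer(meta$seed), constants = constants)
  structure(rec, class = c("esa_session", "data.frame"),
            patient = patient, config = config)
}

#' Write session statistics as JSON
#'
#' @param stats A `session_stats` object from [summarize_session()], or a
#'   named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  if (inherits(stats, "session_stats")) stats <- unclass(stats)
  if (is.list(stats)) {
    stats <- rapply(stats, unclass, classes = "session_stats", how = "replace")
  }
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest
#'
#' Metadata block identifying a run: package version, a hash of the
#' constants, the seeds in play, the invoking command line and a timestamp.
#' Batch outputs embed it so any result can be regenerated from its seeds.
#'
#' @param config A [session_config()] or an `esa_constants` object.
#' @param seeds Named list/vector of seeds used by the run.
#' @param command Invoking command line (default: this R invocation).
#' @return A named list.
#' @export
run_manifest <- function(config, seeds = NULL,
                         command = paste(commandArgs(), collapse = " ")) {
  cst <- if (inherits(config, "session_config")) config$constants else config
  list(
    tool = "eposim",
    version = as.character(utils::packageVersion("eposim")),
    config_hash = config_hash(cst),
    seeds = seeds,
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

# order-independent digest of the constants (polynomial rolling hash over
# the serialized key=value lines; mod 2^31-1 keeps exact double arithmetic)
config_hash <- function(cst) {
  txt <- paste(sprintf("%s=%s", names(cst)[order(names(cst))],
                       vapply(cst[order(names(cst))], function(v)
                         paste(sprintf("%.17g", as.numeric(v)), collapse = ","),
                         character(1))),
               collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}
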