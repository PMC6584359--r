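# Delimited-text serialization for feature spaces, responses and results,
# plus a small command-line entry point. Containers are TSV with a JSON
# header line (prefixed "#") carrying rate, name and subspace partition, so
# files remain self-describing, diffable and tool-agnostic.

#' Write a feature space (or response matrix) to TSV
#'
#' @param fs a [feature_space()], or a plain matrix with `rate` given.
#' @param path output path.
#' @param rate sampling rate when `fs` is a bare matrix.
#' @export
write_feature_tsv <- function(fs, path, rate = NULL) {
  if (!inherits(fs, "feature_space")) {
    stopifnot(!is.null(rate))
    fs <- feature_space(as.matrix(fs), rate, "response")
  }
  hdr <- jsonlite::toJSON(list(rate_hz = fs$rate, name = fs$name,
                               subspaces = fs$subspaces), auto_unbox = TRUE)
  dat <- fs$data
  if (is.null(colnames(dat)))
    colnames(dat) <- paste0("ch", seq_len(ncol(dat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(dat, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a feature space written by [write_feature_tsv()]
#'
#' @param path input path.
#' @return A [feature_space()].
#' @export
read_feature_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) stop_invalid("missing header line in ", path)
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  dat <- utils::read.delim(path, comment.char = "#")
  subs <- lapply(meta$subspaces, as.integer)
  feature_space(as.matrix(dat), meta$rate_hz, meta$name, subs)
}

#' Command-line entry point
#'
#' Dispatches `trfpid <command> [--key value ...]` with commands:
#' `simulate` (config-driven synthetic dataset; JSON config with fields
#' duration_s, rate, n_channels, snr, seed), `features` (audio/events to
#' feature TSVs), and `pid` (PID of two prediction files about an observed
#' file, JSON output). Used by the `inst/cli/trfpid` script.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched command.
#' @export
trfpid_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: trfpid <simulate|features|pid> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1L]
  opts <- parse_cli_opts(args[-1L])
  switch(
    cmd,
    simulate = cli_simulate(opts),
    features = cli_features(opts),
    pid = cli_pid(opts),
    stop_invalid("unknown command: ", cmd))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop_invalid("expected --option: ", args[i])
    opts[[sub("^--", "", args[i])]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_simulate <- function(opts) {
  cfg <- if (!is.null(opts$config)) jsonlite::fromJSON(opts$config) else list()
  g <- function(nm, dflt) if (is.null(cfg[[nm]])) dflt else cfg[[nm]]
  out <- opts$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(g("seed", 1))
  fs <- simulate_features(g("duration_s", 60), g("rate", 40),
                          g("n_channels", 31), g("smoothness", 0.05), seed)
  trf <- make_ground_truth_trf(rate = g("rate", 40),
                               n_channels = g("n_channels", 31), seed = seed)
  resp <- simulate_response(fs, trf, snr = g("snr", 10), seed = seed)
  ev <- simulate_events(g("duration_s", 60), seed = seed)
  write_feature_tsv(fs, file.path(out, "features.tsv"))
  write_feature_tsv(resp$repeats, file.path(out, "response.tsv"),
                    rate = g("rate", 40))
  write_events_tsv(ev, file.path(out, "events.tsv"))
  message("wrote features.tsv, response.tsv, events.tsv to ", out)
  invisible(out)
}

cli_features <- function(opts) {
  spaces <- strsplit(opts$spaces %||% "Sg", ",")[[1L]]
  rate <- as.numeric(opts$rate %||% "40")
  built <- list()
  if (any(spaces %in% c("Sg", "Env", "Deriv", "Gabor"))) {
    wav <- read_wav(opts$audio)
    sg <- log_mel_spectrogram(wav)
    if ("Sg" %in% spaces) built$Sg <- preprocess(sg, rate)
    if ("Env" %in% spaces) built$Env <- preprocess(envelope(sg), rate)
    if ("Deriv" %in% spaces)
      built$Deriv <- preprocess(halfwave_derivative(sg), rate)
    if ("Gabor" %in% spaces)
      built$Gabor <- preprocess(gabor_filterbank(sg), rate)
  }
  if (any(spaces %in% c("PhOn", "Art"))) {
    ev <- read_events_tsv(opts$events)
    ns <- as.integer(ceiling(max(ev$onset_s) * rate) + rate)
    for (sp in intersect(spaces, c("PhOn", "Art")))
      built[[sp]] <- preprocess(event_features(ev, sp, rate, ns), rate)
  }
  joint <- concat_subspaces(built[spaces])
  write_feature_tsv(joint, opts$out %||% "features.tsv")
  invisible(joint)
}

cli_pid <- function(opts) {
  x <- read_feature_tsv(opts$x)$data[, 1L]
  y <- read_feature_tsv(opts$y)$data[, 1L]
  t <- read_feature_tsv(opts$t)$data[, 1L]
  seed <- as.integer(opts$seed %||% "1")
  pid <- pid_ccs(x, y, t, n_mc = as.numeric(opts$n_mc %||% "1e5"),
                 seed = seed)
  res <- pid[c("redundancy", "unique_x", "unique_y", "synergy",
               "mi_x", "mi_y", "mi_joint", "n", "n_mc")]
  res$units <- "bits"; res$seed <- seed
  json <- jsonlite::toJSON(res, auto_unbox = TRUE, digits = NA)
  if (!is.null(opts$out)) writeLines(json, opts$out) else cat(json, "\n")
  invisible(pid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
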