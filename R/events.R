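# Event tables: phoneme onsets with labels, manner-of-articulation classes
# and (via a phoneme mapping table) articulatory feature sets. Annotations
# can come from Praat TextGrids (phone tier) or plain TSV files; a default
# phoneme -> articulatory-feature / manner-class mapping ships as package
# data and can be replaced by the user.

#' Construct an event table
#'
#' @param onset_s event onset times in seconds (strictly increasing).
#' @param phoneme phoneme labels.
#' @param class optional manner-of-articulation class per event, one of
#'   "vowel", "nasal", "plosive", "fricative" (NA allowed = excluded from
#'   class-based analyses).
#' @return A data.frame of class `event_table`.
#' @export
event_table <- function(onset_s, phoneme, class = NA_character_) {
  onset_s <- as.numeric(onset_s)
  if (is.unsorted(onset_s, strictly = TRUE))
    stop_invalid("onsets must be strictly increasing")
  df <- data.frame(onset_s = onset_s,
                   phoneme = as.character(phoneme),
                   class = rep_len(as.character(class), length(onset_s)),
                   stringsAsFactors = FALSE)
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read events from a TSV file
#'
#' Expects at least columns `onset_s` and `phoneme`; a `class` column is kept
#' if present, otherwise classes are filled from the mapping table.
#'
#' @param path TSV file path.
#' @param mapping phoneme mapping data.frame (see [phoneme_map()]); used to
#'   fill missing manner classes.
#' @return An [event_table()].
#' @export
read_events_tsv <- function(path, mapping = phoneme_map()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "phoneme") %in% names(df)))
    stop_invalid("TSV must have columns onset_s and phoneme")
  cls <- if ("class" %in% names(df)) as.character(df$class) else
    rep(NA_character_, nrow(df))
  fill <- is.na(cls)
  cls[fill] <- mapping$manner_class[match(toupper(df$phoneme[fill]),
                                          mapping$phoneme)]
  event_table(df$onset_s, df$phoneme, cls)
}

#' Write events to a TSV file
#'
#' @param events an [event_table()].
#' @param path output file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read phoneme onsets from a Praat TextGrid
#'
#' Minimal parser for long-format TextGrids: extracts the interval tier whose
#' name matches `tier` and returns the onset (xmin) of every non-empty,
#' non-silence interval.
#'
#' @param path TextGrid file path.
#' @param tier tier name (regular expression, case-insensitive);
#'   default "phone".
#' @param mapping phoneme mapping used to fill manner classes.
#' @return An [event_table()].
#' @export
read_textgrid <- function(path, tier = "phone", mapping = phoneme_map()) {
  lines <- readLines(path, warn = FALSE)
  get_num <- function(x) as.numeric(sub(".*=\\s*", "", x))
  get_str <- function(x) gsub("^\\s*\"|\"\\s*$", "",
                              sub(".*=\\s*", "", x))
  item_starts <- grep("^\\s*item\\s*\\[", lines)
  if (!length(item_starts)) stop_invalid("no tiers found in TextGrid")
  item_ends <- c(item_starts[-1L] - 1L, length(lines))
  onsets <- numeric(0); labs <- character(0)
  for (i in seq_along(item_starts)) {
    block <- lines[item_starts[i]:item_ends[i]]
    nm_line <- grep("^\\s*name\\s*=", block, value = TRUE)
    if (!length(nm_line)) next
    if (!grepl(tier, get_str(nm_line[1L]), ignore.case = TRUE)) next
    xmin <- get_num(grep("^\\s*xmin\\s*=", block, value = TRUE))
    text <- get_str(grep("^\\s*text\\s*=", block, value = TRUE))
    # first xmin is the tier's own start time; intervals follow in order
    if (length(xmin) == length(text) + 2L) xmin <- xmin[-(1:2)] else
      xmin <- utils::tail(xmin, length(text))
    keep <- !(text %in% c("", "sil", "sp", "SIL", "SP", "<p:>"))
    onsets <- c(onsets, xmin[keep]); labs <- c(labs, text[keep])
  }
  if (!length(onsets)) stop_invalid("tier '", tier, "' not found or empty")
  o <- order(onsets)
  cls <- mapping$manner_class[match(toupper(labs[o]), mapping$phoneme)]
  event_table(onsets[o], labs[o], cls)
}

#' Default phoneme to articulatory-feature and manner-class mapping
#'
#' A 23-feature binary articulatory description plus a manner class for the
#' ARPAbet phoneme inventory (and the synthetic labels syn1..syn4 emitted by
#' [simulate_events()]). This default follows the standard voicing /
#' manner / place / vowel-position scheme used in speech-neuroscience
#' encoding studies; pass your own table with the same columns to override.
#'
#' @param path optional path to a user TSV with columns `phoneme`,
#'   `manner_class`, and 23 binary feature columns.
#' @return data.frame with phoneme, manner_class and 23 0/1 feature columns.
#' @export
phoneme_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phoneme_articulatory_map.tsv",
                        package = "trfpid", mustWork = TRUE)
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  feat_cols <- setdiff(names(map), c("phoneme", "manner_class"))
  if (length(feat_cols) != 23L)
    stop_invalid("mapping must carry exactly 23 feature columns, got ",
                 length(feat_cols))
  map
}

#' Binary impulse feature spaces from events
#'
#' `PhOn` inserts a unit impulse at the sample nearest each phoneme onset in
#' a single binary channel (onset-to-sample rounding: nearest, ties toward
#' the earlier sample). `Art` does the same in each of the 23 articulatory
#' feature channels named by the event's phoneme in the mapping table.
#'
#' @param events an [event_table()].
#' @param mode "PhOn" or "Art".
#' @param rate sampling rate in Hz (impulse trains are constructed directly
#'   at the modelling rate, typically 40 Hz).
#' @param n_samples length of the output in samples.
#' @param mapping phoneme mapping table (Art mode), see [phoneme_map()].
#' @return A [feature_space()] named "PhOn" (1 channel) or "Art" (23).
#' @export
event_features <- function(events, mode = c("PhOn", "Art"), rate = 40,
                           n_samples, mapping = phoneme_map()) {
  mode <- match.arg(mode)
  assert_scalar_num(rate, "rate", positive = TRUE)
  bad <- which(events$onset_s >= n_samples / rate | events$onset_s < 0)
  if (length(bad))
    stop_invalid("onsets beyond duration at rows: ",
                 paste(utils::head(bad, 10L), collapse = ", "))
  # nearest sample, ties toward the earlier sample (0-based index)
  idx <- ceiling(events$onset_s * rate - 0.5) + 1L
  idx[idx < 1L] <- 1L
  if (mode == "PhOn") {
    m <- matrix(0, n_samples, 1L)
    m[idx, 1L] <- 1
    return(feature_space(m, rate, "PhOn"))
  }
  feat_cols <- setdiff(names(mapping), c("phoneme", "manner_class"))
  m <- matrix(0, n_samples, length(feat_cols),
              dimnames = list(NULL, feat_cols))
  rows <- match(toupper(events$phoneme), mapping$phoneme)
  if (anyNA(rows))
    stop_invalid("phonemes missing from mapping: ",
                 paste(unique(events$phoneme[is.na(rows)]), collapse = ", "))
  fm <- as.matrix(mapping[rows, feat_cols])
  for (e in seq_along(idx))
    m[idx[e], ] <- pmax(m[idx[e], ], fm[e, ])
  feature_space(m, rate, "Art")
}
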