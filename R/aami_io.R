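# AAMI class mapping, record split conventions for the MIT-BIH arrhythmia
# database, beat filtering, and plain-text record I/O.

.code_map <- c(
  `1` = "N", `2` = "N", `3` = "N", `34` = "N", `11` = "N",
  `8` = "S", `4` = "S", `7` = "S", `9` = "S",
  `5` = "V", `10` = "V",
  `6` = "F",
  `12` = "Q", `38` = "Q", `13` = "Q"
)

.symbol_map <- c(
  N = "N", L = "N", R = "N", e = "N", j = "N",
  A = "S", a = "S", J = "S", S = "S",
  V = "V", E = "V",
  F = "F",
  `/` = "Q", f = "Q", Q = "Q"
)

#' Map MIT-BIH annotation codes or symbols to AAMI classes
#'
#' Numeric annotation codes follow the standard grouping (e.g. premature
#' ventricular contraction, code 5, maps to V; fusion of ventricular and
#' normal, code 6, maps to F; paced and unclassified beats map to Q).
#' Character input is interpreted as WFDB annotation symbols
#' (N, L, R, e, j -> N; A, a, J, S -> S; V, E -> V; F -> F; /, f, Q -> Q).
#' Unknown codes raise an error rather than silently mapping to N.
#'
#' @param code integer annotation codes or character annotation symbols.
#' @return character vector of AAMI classes (N, S, V, F, Q).
#' @examples
#' map_to_aami(5) # "V"
#' map_to_aami(c("V", "A", "/")) # "V" "S" "Q"
#' @export
map_to_aami <- function(code) {
  map <- if (is.character(code)) .symbol_map else .code_map
  key <- as.character(code)
  out <- map[key]
  if (anyNA(out)) {
    stop("unknown annotation code: ",
         paste(unique(key[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Filter beats for training and evaluation
#'
#' Drops all Q-class beats (paced and unclassified, excluded from the
#' four-class task) and, for every index in the user-supplied
#' `exclusion_list` (e.g. low signal quality beats), that beat together with
#' its immediate predecessor and successor.
#'
#' @param beats data frame with at least a column `aami_class`, rows in time
#'   order.
#' @param exclusion_list integer row indices of beats to exclude (with their
#'   neighbours).
#' @return list with `beats` (kept rows) and `report` (named counts of
#'   dropped beats by reason: `Q`, `excluded`).
#' @export
filter_beats <- function(beats, exclusion_list = integer(0)) {
  stopifnot(is.data.frame(beats), "aami_class" %in% names(beats))
  n <- nrow(beats)
  drop_q <- beats$aami_class == "Q"
  drop_ex <- rep(FALSE, n)
  for (i in exclusion_list) {
    drop_ex[intersect((i - 1):(i + 1), seq_len(n))] <- TRUE
  }
  keep <- !(drop_q | drop_ex)
  list(
    beats = beats[keep, , drop = FALSE],
    report = c(Q = sum(drop_q & !drop_ex), excluded = sum(drop_ex))
  )
}

#' Standard MIT-BIH record split
#'
#' The conventional equal division of the 44 non-paced records into
#' training and testing sets, with the four paced records (102, 104, 107,
#' 217) excluded from both.
#'
#' @return list with integer vectors `train_ids`, `test_ids`,
#'   `excluded_ids`.
#' @export
default_record_split <- function() {
  list(
    train_ids = c(101, 106, 108, 109, 112, 114, 115, 116, 118, 119, 122,
                  124, 201, 203, 205, 207, 208, 209, 215, 220, 223, 230),
    test_ids = c(100, 103, 105, 111, 113, 117, 121, 123, 200, 202, 210,
                 212, 213, 214, 219, 221, 222, 228, 231, 232, 233, 234),
    excluded_ids = c(102, 104, 107, 217)
  )
}

#' Write a record to plain-text files
#'
#' Serializes a record as three files under `dir`: `<name>_signal.csv`
#' (one column per lead, mV), `<name>_annotations.csv` (columns `sample`,
#' `aami_class`) and `<name>_header.json` (sampling rate, leads, patient
#' id).
#'
#' @param record a [synth_record()] or a list with `signal`, `fs`,
#'   `annotations`, `patient_id`.
#' @param dir output directory (created if missing).
#' @param name file-name stem; defaults to the record's `patient_id`.
#' @param lead lead name written to the header.
#' @return invisibly, the three file paths.
#' @export
write_record <- function(record, dir, name = record$patient_id,
                         lead = "II") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, paste0(name, "_signal.csv"))
  ann_path <- file.path(dir, paste0(name, "_annotations.csv"))
  hdr_path <- file.path(dir, paste0(name, "_header.json"))
  sig <- stats::setNames(data.frame(record$signal), lead)
  utils::write.csv(sig, sig_path, row.names = FALSE)
  utils::write.csv(record$annotations, ann_path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = record$fs, leads = lead, patient_id = record$patient_id),
    hdr_path, auto_unbox = TRUE
  )
  invisible(c(signal = sig_path, annotations = ann_path, header = hdr_path))
}

#' Read a record from plain-text files
#'
#' Reads the three files written by [write_record()]. The preferred lead is
#' selected by column name; if absent, the first signal column is used with
#' a warning. Annotation classes are taken from an `aami_class` column, or
#' mapped via [map_to_aami()] from a `mitbih_code` (or symbol) column.
#'
#' @param path_prefix path stem, i.e. `file.path(dir, name)`.
#' @param lead_preference preferred lead name.
#' @return list with `signal`, `fs`, `annotations` (data frame `sample`,
#'   `aami_class`), `patient_id`, `lead`.
#' @export
read_record <- function(path_prefix, lead_preference = "II") {
  sig_path <- paste0(path_prefix, "_signal.csv")
  ann_path <- paste0(path_prefix, "_annotations.csv")
  hdr_path <- paste0(path_prefix, "_header.json")
  for (p in c(sig_path, ann_path, hdr_path)) {
    if (!file.exists(p)) stop("missing record file: ", p, call. = FALSE)
  }
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  sig <- utils::read.csv(sig_path)
  if (lead_preference %in% names(sig)) {
    lead <- lead_preference
  } else {
    lead <- names(sig)[1]
    warning("lead ", lead_preference, " not present; falling back to ", lead)
  }
  ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
  if (!"aami_class" %in% names(ann)) {
    code_col <- intersect(c("mitbih_code", "symbol"), names(ann))
    if (length(code_col) == 0) {
      stop("annotation file has neither aami_class nor mitbih_code",
           call. = FALSE)
    }
    ann$aami_class <- map_to_aami(ann[[code_col[1]]])
  }
  list(
    signal = sig[[lead]],
    fs = hdr$fs,
    annotations = ann[, c("sample", "aami_class")],
    patient_id = hdr$patient_id,
    lead = lead
  )
}
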