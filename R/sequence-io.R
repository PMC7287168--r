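#' Read site-centered sequence windows from FASTA
#'
#' Reads a (possibly line-wrapped) FASTA file into a tibble of sequence
#' records. Sequences are uppercased and RNA-style `U` is mapped to `T`;
#' any residue outside `A`, `C`, `G`, `T`, `N` is an error reporting the
#' offending record and position. Window length is *not* enforced here —
#' the encoders check it against their configured width.
#'
#' Labels for training data are conventionally supplied by reading the
#' positive and negative FASTA files separately with `label = 1` and
#' `label = 0` and row-binding the results; alternatively join a
#' two-column id/label table read with [read_label_tsv()].
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label (`1` = methylated site, `0` = not)
#'   applied to every record in the file, or `NA` for unlabeled queries.
#' @return A tibble with columns `id` (character), `seq` (character,
#'   uppercase A/C/G/T/N) and `label` (integer, possibly `NA`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acguACGTN"), fa)
#' read_site_fasta(fa, label = 1)
#' @export
read_site_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "methsite_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Malformed FASTA in '", path, "': ", conditionMessage(e)),
            class = "methsite_parse_error")
    }
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file '", path, "' contains no records"),
          class = "methsite_parse_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- clean_sequences(unname(as.character(set)), ids)
  tibble(id = ids, seq = seqs, label = as.integer(rep(label, length(ids))))
}

#' Write sequence records to FASTA
#'
#' @param records A tibble with columns `id` and `seq` (as returned by
#'   [read_site_fasta()] or [simulate_sites()]).
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_site_fasta <- function(records, path, width = 60L) {
  check_record_frame(records)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a record-id / label table
#'
#' Reads a two-column headerless TSV of `id<TAB>label` suitable for joining
#' onto records read from a single mixed FASTA file.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `id` and `label`.
#' @export
read_label_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("id", "label"),
                         col_types = readr::cols(
                           id = readr::col_character(),
                           label = readr::col_integer()
                         ), progress = FALSE)
  bad <- !tab$label %in% c(0L, 1L)
  if (any(bad)) {
    abort(paste0("Labels must be 0/1; offending ids: ",
                 paste(utils::head(tab$id[bad], 5), collapse = ", ")),
          class = "methsite_validation_error")
  }
  tab
}

#' Extract a fixed-width window centered on a candidate site
#'
#' Returns the subsequence of `seq` of length `width` whose central
#' position is `center` (1-based). Positions falling outside the sequence
#' on either side are padded with the gap character `N`, so the candidate
#' base always sits exactly at position `(width + 1) / 2`.
#'
#' @param seq A single sequence string (A/C/G/T/N, uppercase).
#' @param center 1-based position of the candidate adenine within `seq`.
#' @param width Odd window width (default 41).
#' @param center_check What to do when the base at `center` is not `A`:
#'   `"warn"` (default), `"error"`, or `"ignore"`.
#' @return A string of length `width`.
#' @examples
#' extract_window("AAAA", center = 1, width = 5)  # "NNAAA"
#' @export
extract_window <- function(seq, center, width = 41L,
                           center_check = c("warn", "error", "ignore")) {
  center_check <- match.arg(center_check)
  stopifnot(is.character(seq), length(seq) == 1L)
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) {
    abort("`width` must be an odd positive integer",
          class = "methsite_config_error")
  }
  L <- nchar(seq)
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > L) {
    abort(sprintf("`center` (%s) out of range 1..%d", center, L),
          class = "methsite_index_error")
  }
  base <- substr(seq, center, center)
  if (base != "A" && center_check != "ignore") {
    msg <- sprintf("base at center position %d is '%s', not 'A'", center, base)
    if (center_check == "error") {
      abort(msg, class = "methsite_validation_error")
    }
    warn(msg)
  }
  h <- (width - 1L) %/% 2L
  lo <- center - h
  hi <- center + h
  core <- substr(seq, max(lo, 1L), min(hi, L))
  paste0(strrep("N", max(0L, 1L - lo)), core, strrep("N", max(0L, hi - L)))
}

#' Check that records match a configured window width
#'
#' @param records Record tibble (columns `id`, `seq`).
#' @param width Required window width.
#' @return `records`, invisibly, if all sequences have length `width`.
#' @export
validate_windows <- function(records, width = 41L) {
  check_record_frame(records)
  len <- nchar(records$seq)
  bad <- which(len != width)
  if (length(bad)) {
    abort(sprintf(
      "%d record(s) do not have window width %d (e.g. '%s' has length %d)",
      length(bad), width, records$id[bad[1]], len[bad[1]]),
      class = "methsite_validation_error")
  }
  invisible(records)
}

# --- internal -----------------------------------------------------------

# uppercase, U->T, and validate alphabet with record/position reporting
clean_sequences <- function(seqs, ids) {
  seqs <- chartr("u", "t", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  bad <- stringr::str_locate(seqs, "[^ACGTN]")[, "start"]
  hit <- which(!is.na(bad))
  if (length(hit)) {
    i <- hit[1]
    abort(sprintf(
      "record '%s' contains illegal character '%s' at position %d",
      ids[i], substr(seqs[i], bad[i], bad[i]), bad[i]),
      class = "methsite_validation_error")
  }
  seqs
}

check_record_frame <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    abort("`records` must be a data frame with columns `id` and `seq`",
          class = "methsite_validation_error")
  }
  invisible(records)
}
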