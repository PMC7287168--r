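# Nucleotide positional specificity (NPS) encoding: per-position orthogonal
# binary codes for the whole window plus position-independent overlapping
# k-mer frequencies for k = 2, 3, 4. For the default 41-nt window this gives
# 4*41 + 16 + 64 + 256 = 500 features.

# orthogonal code table; the slot order means slot 1 is the G indicator,
# slot 2 the C indicator, slot 3 the T indicator and slot 4 the A indicator.
# N codes as all zeros.
NPS_CODES <- rbind(
  A = c(0, 0, 0, 1),
  T = c(0, 0, 1, 0),
  C = c(0, 1, 0, 0),
  G = c(1, 0, 0, 0),
  N = c(0, 0, 0, 0)
)
NPS_SLOT_BASE <- c("G", "C", "T", "A")

#' Positional orthogonal binary encoding of a window
#'
#' Each position contributes four 0/1 entries using the code table
#' A = (0,0,0,1), T = (0,0,1,0), C = (0,1,0,0), G = (1,0,0,0) and
#' N = (0,0,0,0); slot j of position p is therefore an indicator for the
#' nucleotide whose code carries the 1 in slot j.
#'
#' @param seq A window string over A/C/G/T/N.
#' @param width Expected window width; the default `nchar(seq)` accepts any
#'   length, pass the configured width to enforce it.
#' @return A named numeric vector of length `4 * width`, names
#'   `pos<p>_<base>`.
#' @examples
#' nps_one_hot("A")  # 0 0 0 1
#' @export
nps_one_hot <- function(seq, width = nchar(seq)) {
  chars <- check_window(seq, width)
  v <- as.vector(t(NPS_CODES[chars, , drop = FALSE]))
  names(v) <- paste0("pos", sprintf("%02d", rep(seq_len(width), each = 4L)),
                     "_", NPS_SLOT_BASE)
  v
}

#' Position-independent k-mer frequencies
#'
#' Counts overlapping k-mers over the window and normalizes by the number
#' of k-length windows containing no `N`; k-mers containing `N` are dropped
#' from both numerator and denominator. If no valid window exists the
#' vector is all zeros.
#'
#' @param seq A window string over A/C/G/T/N with `nchar(seq) >= k`.
#' @param k k-mer size.
#' @return A named numeric vector of length `4^k`, k-mers in lexicographic
#'   order (AA, AC, AG, AT, CA, ...).
#' @examples
#' kmer_frequencies("ACGT", 2)[c("AC", "CG", "GT")]  # each 1/3
#' @export
kmer_frequencies <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1", class = "methsite_config_error")
  L <- nchar(seq)
  if (L < k) {
    abort(sprintf("sequence length %d is shorter than k = %d", L, k),
          class = "methsite_validation_error")
  }
  starts <- seq_len(L - k + 1L)
  mers <- substring(seq, starts, starts + k - 1L)
  mers <- mers[!grepl("N", mers, fixed = TRUE)]
  lv <- all_kmers(k)
  counts <- table(factor(mers, levels = lv))
  out <- as.numeric(counts)
  if (length(mers)) out <- out / length(mers)
  names(out) <- lv
  out
}

#' NPS feature encoding of sequence windows
#'
#' Encodes each record's window as the concatenation of the positional
#' binary block and the k-mer frequency blocks (k = 2, 3, 4 by default);
#' with the default 41-nt width this is the 500-dimensional NPS vector.
#' Feature names are prefixed `nps_` and the block layout
#' (binary, then k-mer blocks in increasing k, k-mers lexicographic) is
#' fixed so feature indices in downstream selection results are stable.
#'
#' @param data A record tibble with columns `id`, `seq` and optionally
#'   `label`, e.g. from [read_site_fasta()] or [simulate_sites()].
#' @param width Window width every sequence must have (default 41).
#' @param kmer_sizes Integer vector of k-mer sizes (default `c(2, 3, 4)`).
#' @return A tibble with columns `id`, `label`, then one numeric column per
#'   feature.
#' @examples
#' sim <- simulate_sites(n_pos = 2, n_neg = 2, seed = 1)
#' ncol(encode_nps(sim)) - 2L  # 500
#' @export
encode_nps <- function(data, width = 41L, kmer_sizes = c(2L, 3L, 4L)) {
  check_record_frame(data)
  validate_windows(data, width)
  validate_alphabet(data)
  rows <- lapply(data$seq, function(s) {
    c(nps_one_hot(s, width),
      unlist(lapply(kmer_sizes, function(k) kmer_frequencies(s, k))))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("nps_", colnames(mat))
  dplyr::bind_cols(
    tibble(id = data$id, label = record_labels(data)),
    as_tibble(mat)
  )
}

# --- internal -----------------------------------------------------------

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  grids <- rev(rep(list(bases), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

check_window <- function(seq, width) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) != width) {
    abort(sprintf("window has length %d, expected %d", nchar(seq), width),
          class = "methsite_validation_error")
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% rownames(NPS_CODES))
  if (length(bad)) {
    abort(sprintf("illegal character '%s' at position %d",
                  chars[bad[1]], bad[1]),
          class = "methsite_validation_error")
  }
  chars
}

validate_alphabet <- function(records) {
  pos <- stringr::str_locate(records$seq, "[^ACGTN]")[, "start"]
  hit <- which(!is.na(pos))
  if (length(hit)) {
    i <- hit[1]
    abort(sprintf("record '%s' contains illegal character at position %d",
                  records$id[i], pos[i]),
          class = "methsite_validation_error")
  }
  invisible(records)
}

record_labels <- function(data) {
  if ("label" %in% names(data)) as.integer(data$label) else
    rep(NA_integer_, nrow(data))
}
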