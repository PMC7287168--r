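#' Simulate a benchmark-like 6mA dataset
#'
#' Generates two balanced classes of fixed-width A/C/G/T windows centered on
#' an adenine, emulating the structure of the rice 6mA benchmark (880
#' methylated and 880 GAGG-motif non-methylated windows of 41 nt):
#'
#' * **positives** draw every position uniformly from A/C/G/T except at the
#'   `informative_positions`, where `informative_base` appears with
#'   probability `0.25 + 0.75 * effect_size`;
#' * **negatives** are uniform background with `motif` embedded so that the
#'   motif's (first) adenine lands exactly on the central position — the
#'   construction used for the real benchmark's negatives, which were drawn
#'   from GAGG-containing coding subsequences.
#'
#' The central base is forced to `A` in both classes, so classes differ only
#' through the positional bias and the motif context, giving the positional
#' one-hot features and the k-mer/dinucleotide features separable signal.
#'
#' @param n_pos,n_neg Number of positive / negative windows (default 880
#'   each, the benchmark size).
#' @param width Window width (odd, default 41).
#' @param effect_size Positional bias strength in positives, in \[0, 1\];
#'   0 means no positional signal, 1 makes `informative_base` certain at
#'   each informative position.
#' @param motif Motif embedded in negatives (default `"GAGG"`); must contain
#'   an `A` and fit inside the window when anchored at the center.
#' @param informative_positions 1-based positions carrying the bias in
#'   positives (default `c(17, 18, 19, 23, 24, 25)`, flanking the center
#'   of a 41-nt window).
#' @param informative_base The biased nucleotide at informative positions
#'   (default `"T"`, chosen outside the motif alphabet so the two signal
#'   channels stay distinct).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A tibble with columns `id`, `seq`, `label` (1 = positive).
#' @examples
#' sim <- simulate_sites(n_pos = 5, n_neg = 5, effect_size = 1, seed = 1)
#' substr(sim$seq, 21, 21)  # all "A"
#' @export
simulate_sites <- function(n_pos = 880L, n_neg = 880L, width = 41L,
                           effect_size = 0.5, motif = "GAGG",
                           informative_positions = c(17L, 18L, 19L, 23L, 24L, 25L),
                           informative_base = "T", seed = 1L) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) {
    abort("`width` must be odd and positive", class = "methsite_config_error")
  }
  if (effect_size < 0 || effect_size > 1) {
    abort("`effect_size` must lie in [0, 1]", class = "methsite_config_error")
  }
  center <- (width + 1L) %/% 2L
  motif <- toupper(motif)
  a_off <- as.integer(regexpr("A", motif, fixed = TRUE))
  if (a_off < 1L) {
    abort("`motif` must contain an 'A' to anchor on the site",
          class = "methsite_config_error")
  }
  m_start <- center - a_off + 1L
  m_end <- m_start + nchar(motif) - 1L
  if (m_start < 1L || m_end > width) {
    abort("`motif` does not fit inside the window when centered on its 'A'",
          class = "methsite_config_error")
  }
  informative_positions <- as.integer(informative_positions)
  if (any(informative_positions < 1L | informative_positions > width)) {
    abort("`informative_positions` out of window range",
          class = "methsite_config_error")
  }
  if (!informative_base %in% c("A", "C", "G", "T")) {
    abort("`informative_base` must be one of A/C/G/T",
          class = "methsite_config_error")
  }

  bases <- c("A", "C", "G", "T")
  p_hit <- 0.25 + 0.75 * effect_size
  withr::with_seed(as.integer(seed), {
    pos <- draw_windows(n_pos, width)
    for (p in informative_positions) {
      hit <- stats::runif(n_pos) < p_hit
      pos[hit, p] <- informative_base
      # misses are uniform over the other three nucleotides
      n_miss <- sum(!hit)
      if (n_miss) {
        pos[!hit, p] <- sample(setdiff(bases, informative_base),
                               n_miss, replace = TRUE)
      }
    }
    pos[, center] <- "A"

    neg <- draw_windows(n_neg, width)
    motif_chars <- strsplit(motif, "")[[1]]
    for (k in seq_along(motif_chars)) {
      neg[, m_start + k - 1L] <- motif_chars[k]
    }
  })
  tibble(
    id = c(sprintf("pos_%04d", seq_len(n_pos)),
           sprintf("neg_%04d", seq_len(n_neg))),
    seq = c(apply(pos, 1, paste0, collapse = ""),
            apply(neg, 1, paste0, collapse = "")),
    label = c(rep(1L, n_pos), rep(0L, n_neg))
  )
}

#' Write a simulated dataset as paired FASTA files plus a manifest
#'
#' @param dir Output directory (created if missing); writes
#'   `positives.fasta`, `negatives.fasta` and `manifest.json` recording the
#'   full generator configuration.
#' @inheritParams simulate_sites
#' @return The record tibble, invisibly.
#' @export
simulate_to_fasta <- function(dir, n_pos = 880L, n_neg = 880L, width = 41L,
                              effect_size = 0.5, motif = "GAGG",
                              informative_positions = c(17L, 18L, 19L, 23L, 24L, 25L),
                              informative_base = "T", seed = 1L) {
  rec <- simulate_sites(n_pos, n_neg, width, effect_size, motif,
                        informative_positions, informative_base, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_site_fasta(dplyr::filter(rec, .data$label == 1L),
                   file.path(dir, "positives.fasta"))
  write_site_fasta(dplyr::filter(rec, .data$label == 0L),
                   file.path(dir, "negatives.fasta"))
  manifest <- list(
    n_pos = n_pos, n_neg = n_neg, width = width, effect_size = effect_size,
    motif = motif, informative_positions = informative_positions,
    informative_base = informative_base, seed = seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

draw_windows <- function(n, width) {
  matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
         nrow = n, ncol = width)
}
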