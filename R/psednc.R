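# Pseudo dinucleotide composition (PseDNC): the 16 dinucleotide frequencies
# plus lambda "correlation factor" tiers summarizing physicochemical
# similarity of dinucleotides at increasing sequence separations, combined
# into a single normalized (16 + lambda)-vector.

DINUCS <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
            "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")

#' Default dinucleotide physicochemical property table
#'
#' Nearest-neighbor thermodynamic parameters for the 16 DNA dinucleotide
#' steps: enthalpy (kcal/mol), entropy (cal/mol/K) and standard free energy
#' at 37 C (kcal/mol), from the unified nearest-neighbor parameter set.
#' These are the three properties the pseudo dinucleotide composition uses
#' for its sequence-order correlation factors. Because the correlation
#' factors are computed from *standardized* property values, any table that
#' is an affine rescaling of this one yields identical features; a
#' different table can be supplied via [read_property_table()].
#'
#' @return A tibble with columns `dinucleotide`, `enthalpy`, `entropy`,
#'   `free_energy` (16 rows, lexicographic order).
#' @export
dinuc_property_table <- function() {
  tibble(
    dinucleotide = DINUCS,
    enthalpy = c(-7.9, -8.4, -7.8, -7.2, -8.5, -8.0, -10.6, -7.8,
                 -8.2, -9.8, -8.0, -8.4, -7.2, -8.2, -8.5, -7.9),
    entropy = c(-22.2, -22.4, -21.0, -20.4, -22.7, -19.9, -27.2, -21.0,
                -22.2, -24.4, -19.9, -22.4, -21.3, -22.2, -22.7, -22.2),
    free_energy = c(-1.00, -1.44, -1.28, -0.88, -1.45, -1.84, -2.17, -1.28,
                    -1.30, -2.24, -1.84, -1.44, -0.58, -1.30, -1.45, -1.00)
  )
}

#' Read a dinucleotide property table from TSV
#'
#' Expects a header row and columns `dinucleotide`, `enthalpy`, `entropy`,
#' `free_energy`; all 16 dinucleotides must be present exactly once.
#'
#' @param path Path to a tab-separated file.
#' @return A property tibble in the same form as [dinuc_property_table()].
#' @export
read_property_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    dinucleotide = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("dinucleotide", "enthalpy", "entropy", "free_energy")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("property table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "methsite_validation_error")
  }
  tab$dinucleotide <- toupper(tab$dinucleotide)
  check_property_table(tab[need])
  tab[need]
}

#' Standardize a dinucleotide property table
#'
#' Each property is centered and scaled over the 16 dinucleotides:
#' `P(D) = (P0(D) - mean(P0)) / SD(P0)` with the population (divide-by-16)
#' standard deviation, so every standardized property has mean 0 and SD 1
#' across the dinucleotides. Standardization is invariant under affine
#' transforms of the raw values.
#'
#' @param raw A property tibble (columns `dinucleotide` plus one numeric
#'   column per property), e.g. [dinuc_property_table()].
#' @return A tibble of the same shape with standardized property values;
#'   the raw table is kept in attribute `"raw"`.
#' @export
standardize_properties <- function(raw) {
  check_property_table(raw)
  out <- raw[order(match(raw$dinucleotide, DINUCS)), , drop = FALSE]
  for (g in setdiff(names(out), "dinucleotide")) {
    x <- out[[g]]
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) {
      abort(paste0("property '", g, "' is constant across dinucleotides ",
                   "(zero SD); cannot standardize"),
            class = "methsite_validation_error")
    }
    out[[g]] <- (x - mean(x)) / s
  }
  attr(out, "raw") <- raw
  out
}

#' Dinucleotide frequencies of a sequence
#'
#' Counts dinucleotides and normalizes to sum 1. Dinucleotides containing
#' `N` are excluded from both count and denominator. `overlap = TRUE`
#' (default) slides by one position; `overlap = FALSE` takes disjoint pairs
#' starting at position 1.
#'
#' @param seq A sequence string over A/C/G/T/N, length >= 2.
#' @param overlap Use overlapping counting (default) or literal
#'   non-overlapping pairs.
#' @return A named numeric 16-vector summing to 1.
#' @examples
#' dinuc_frequencies("ACGT")[c("AC", "CG", "GT")]            # 1/3 each
#' dinuc_frequencies("ACGT", overlap = FALSE)[c("AC", "GT")] # 1/2 each
#' @export
dinuc_frequencies <- function(seq, overlap = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < 2L) {
    abort("sequence must have length >= 2", class = "methsite_validation_error")
  }
  starts <- if (overlap) seq_len(L - 1L) else seq(1L, L - 1L, by = 2L)
  pairs <- substring(seq, starts, starts + 1L)
  pairs <- pairs[!grepl("N", pairs, fixed = TRUE)]
  if (!length(pairs)) {
    abort("sequence contains no N-free dinucleotide",
          class = "methsite_validation_error")
  }
  counts <- table(factor(pairs, levels = DINUCS))
  out <- as.numeric(counts) / length(pairs)
  names(out) <- DINUCS
  out
}

#' Sequence-order correlation factors
#'
#' The j-th tier correlation factor is the average, over all positions i,
#' of the correlation function between the dinucleotides starting at i and
#' at i + j:
#' `C(i, i+j) = mean_g (P_g(D_i) - P_g(D_{i+j}))^2` over the standardized
#' properties, averaged over `i = 1 .. L - j - 1`. Terms whose dinucleotides
#' contain `N` are dropped and the denominator adjusted; a tier with no
#' valid term is 0.
#'
#' @param seq A sequence string over A/C/G/T/N of length L.
#' @param lambda Number of tiers; must satisfy `lambda < L - 1`.
#' @param properties Standardized property table from
#'   [standardize_properties()] (a raw table is standardized on the fly).
#' @return A numeric vector `theta[1..lambda]`, each >= 0.
#' @export
theta_factors <- function(seq, lambda = 6L,
                          properties = standardize_properties(dinuc_property_table())) {
  stopifnot(is.character(seq), length(seq) == 1L)
  lambda <- as.integer(lambda)
  L <- nchar(seq)
  if (lambda < 1L || lambda >= L - 1L) {
    abort(sprintf("`lambda` must satisfy 1 <= lambda < L - 1 = %d", L - 1L),
          class = "methsite_config_error")
  }
  P <- property_matrix(properties)
  D2 <- dinuc_sqdiff_matrix(P)
  idx <- dinuc_index(seq)          # NA where the dinucleotide contains N
  vapply(seq_len(lambda), function(j) {
    i <- seq_len(L - j - 1L)
    a <- idx[i]
    b <- idx[i + j]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(0)
    mean(D2[cbind(a[ok], b[ok])])
  }, numeric(1))
}

#' Correlation function between two dinucleotides of a sequence
#'
#' `C(i, i+j)`: the mean over the standardized physicochemical properties of
#' the squared difference between the dinucleotide starting at position `i`
#' and the one starting at `i + j`.
#'
#' @inheritParams theta_factors
#' @param i 1-based start position of the first dinucleotide.
#' @param j Tier (separation between the two dinucleotide start positions).
#' @return A non-negative scalar, or `NA` if either dinucleotide contains `N`.
#' @export
dinuc_correlation <- function(seq, i, j,
                              properties = standardize_properties(dinuc_property_table())) {
  L <- nchar(seq)
  if (i < 1L || i + j + 1L > L) {
    abort("dinucleotide positions out of range", class = "methsite_index_error")
  }
  idx <- dinuc_index(seq)
  a <- idx[i]
  b <- idx[i + j]
  if (is.na(a) || is.na(b)) return(NA_real_)
  P <- property_matrix(properties)
  mean((P[a, ] - P[b, ])^2)
}

#' Pseudo dinucleotide composition encoding of sequence windows
#'
#' Encodes each record as the (16 + lambda)-dimensional PseDNC vector
#' `d`: the first 16 components are dampened dinucleotide frequencies and
#' the last `lambda` are weighted correlation factors, jointly normalized,
#' \deqn{d_u = f_u / (\sum f + w \sum\theta)\ (u \le 16),\quad
#'       d_u = w\,\theta_{u-16} / (\sum f + w \sum\theta)\ (u > 16),}
#' so the whole vector sums to 1. With the default `lambda = 6` this gives
#' 22 features per window.
#'
#' @inheritParams encode_nps
#' @param lambda Number of correlation tiers (default 6).
#' @param w Weight factor balancing frequency and sequence-order components,
#'   in (0, 1\] (default 0.1).
#' @param overlap Dinucleotide counting mode, see [dinuc_frequencies()].
#' @param properties Raw or standardized property table.
#' @return A tibble with columns `id`, `label`, then `psednc_f_AA` ...
#'   `psednc_f_TT`, `psednc_theta1` ... `psednc_theta<lambda>`.
#' @examples
#' sim <- simulate_sites(n_pos = 2, n_neg = 2, seed = 1)
#' ncol(encode_psednc(sim)) - 2L  # 22
#' @export
encode_psednc <- function(data, width = 41L, lambda = 6L, w = 0.1,
                          overlap = TRUE, properties = dinuc_property_table()) {
  check_record_frame(data)
  validate_windows(data, width)
  validate_alphabet(data)
  if (w <= 0 || w > 1) {
    abort("`w` must lie in (0, 1]", class = "methsite_config_error")
  }
  std <- if (is_standardized(properties)) properties else
    standardize_properties(properties)
  rows <- lapply(data$seq, function(s) {
    psednc_vector(s, lambda = lambda, w = w, overlap = overlap,
                  properties = std)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("psednc_",
                          c(paste0("f_", DINUCS), paste0("theta", seq_len(lambda))))
  dplyr::bind_cols(
    tibble(id = data$id, label = record_labels(data)),
    as_tibble(mat)
  )
}

#' PseDNC vector of a single sequence
#'
#' @inheritParams theta_factors
#' @inheritParams encode_psednc
#' @param seq A single sequence string.
#' @return Numeric vector of length `16 + lambda` summing to 1.
#' @export
psednc_vector <- function(seq, lambda = 6L, w = 0.1, overlap = TRUE,
                          properties = standardize_properties(dinuc_property_table())) {
  std <- if (is_standardized(properties)) properties else
    standardize_properties(properties)
  f <- dinuc_frequencies(seq, overlap = overlap)
  th <- theta_factors(seq, lambda = lambda, properties = std)
  denom <- sum(f) + w * sum(th)
  c(f / denom, w * th / denom)
}

# --- internal -----------------------------------------------------------

check_property_table <- function(raw) {
  if (!is.data.frame(raw) || !"dinucleotide" %in% names(raw)) {
    abort("property table must have a `dinucleotide` column",
          class = "methsite_validation_error")
  }
  miss <- setdiff(DINUCS, raw$dinucleotide)
  if (length(miss)) {
    abort(paste0("property table is missing dinucleotide(s): ",
                 paste(miss, collapse = ", ")),
          class = "methsite_validation_error")
  }
  if (anyDuplicated(raw$dinucleotide)) {
    abort("property table has duplicated dinucleotides",
          class = "methsite_validation_error")
  }
  if (ncol(raw) < 2L) {
    abort("property table needs at least one property column",
          class = "methsite_validation_error")
  }
  invisible(raw)
}

is_standardized <- function(tab) {
  !is.null(attr(tab, "raw"))
}

property_matrix <- function(std) {
  m <- as.matrix(std[match(DINUCS, std$dinucleotide),
                     setdiff(names(std), "dinucleotide")])
  rownames(m) <- DINUCS
  m
}

# 16 x 16 matrix of mean squared standardized property differences
dinuc_sqdiff_matrix <- function(P) {
  mu <- ncol(P)
  out <- matrix(0, 16L, 16L, dimnames = list(DINUCS, DINUCS))
  for (g in seq_len(mu)) {
    out <- out + outer(P[, g], P[, g], function(a, b) (a - b)^2)
  }
  out / mu
}

# index of the dinucleotide starting at each position; NA when it has an N
dinuc_index <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))  # NA for N
  L <- length(chars)
  a <- code[-L]
  b <- code[-1L]
  (a - 1L) * 4L + b
}
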