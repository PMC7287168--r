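# Independent oracles and small fixture generators used across the suite.

DINUCS16 <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
              "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")

random_windows <- function(n, width = 41L, seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste0(sample(c("A", "C", "G", "T"), width, replace = TRUE),
             collapse = "")
    }, character(1))
  })
}

# Direct transcription of the pseudo dinucleotide composition equations:
# standardization of the raw property table, dinucleotide frequencies,
# tiered correlation factors by explicit double loop, and the two-branch
# normalization. Independent of the package's vectorized implementation.
naive_psednc <- function(seq, lambda, w = 0.1, overlap = TRUE,
                         raw = dinuc_property_table()) {
  P <- as.matrix(raw[match(DINUCS16, raw$dinucleotide),
                     c("enthalpy", "entropy", "free_energy")])
  P <- apply(P, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  rownames(P) <- DINUCS16
  L <- nchar(seq)
  starts <- if (overlap) seq_len(L - 1L) else seq(1L, L - 1L, by = 2L)
  pairs <- substring(seq, starts, starts + 1L)
  f <- vapply(DINUCS16, function(d) sum(pairs == d), numeric(1)) /
    length(pairs)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(L - j - 1L)) {
      Di <- substring(seq, i, i + 1L)
      Dj <- substring(seq, i + j, i + j + 1L)
      acc <- acc + mean((P[Di, ] - P[Dj, ])^2)
    }
    theta[j] <- acc / (L - j - 1L)
  }
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

# Explicit two-group one-way ANOVA F from the defining sums of squares.
oracle_f <- function(x, y) {
  x0 <- x[y == 0]
  x1 <- x[y == 1]
  n <- length(x)
  gm <- mean(x)
  ssb <- length(x0) * (mean(x0) - gm)^2 + length(x1) * (mean(x1) - gm)^2
  ssw <- sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)
  if (ssb <= 0) return(0)
  if (ssw <= 0) return(Inf)
  (ssb / 1) / (ssw / (n - 2))
}

# Mann-Whitney AUC by brute-force pair counting, ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Tiny separable labeled feature frame for model tests.
toy_separable <- function(n_per_class = 20L, seed = 1L) {
  withr::with_seed(seed, {
    x1 <- c(rnorm(n_per_class, -2, 0.3), rnorm(n_per_class, 2, 0.3))
    x2 <- rnorm(2 * n_per_class)
  })
  tibble::tibble(
    id = sprintf("t%02d", seq_len(2L * n_per_class)),
    label = rep(c(0L, 1L), each = n_per_class),
    f1 = x1, f2 = x2
  )
}
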