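test_that("property standardization yields mean 0, SD 1 per property", {
  std <- standardize_properties(dinuc_property_table())
  for (g in c("enthalpy", "entropy", "free_energy")) {
    expect_equal(mean(std[[g]]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(std[[g]]^2)), 1, tolerance = 1e-12)
  }
})

test_that("standardization is affine-invariant and rejects degenerate input", {
  raw <- dinuc_property_table()
  shifted <- raw
  shifted$enthalpy <- 3.7 * raw$enthalpy - 11
  expect_equal(standardize_properties(shifted)$enthalpy,
               standardize_properties(raw)$enthalpy, tolerance = 1e-12)

  flat <- raw
  flat$entropy <- 1
  expect_error(standardize_properties(flat), "entropy",
               class = "methsite_validation_error")
  expect_error(standardize_properties(raw[-1, ]), "AA",
               class = "methsite_validation_error")

  ranks <- tibble::tibble(dinucleotide = raw$dinucleotide, p = 1:16)
  std <- standardize_properties(ranks)
  expect_equal(mean(std$p), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(std$p^2)), 1, tolerance = 1e-12)
})

test_that("property tables load from TSV and are validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dinuc_property_table(), path)
  expect_equal(read_property_table(path), dinuc_property_table())
  truncated <- dinuc_property_table()[1:10, ]
  readr::write_tsv(truncated, path)
  expect_error(read_property_table(path), class = "methsite_validation_error")
})

test_that("dinucleotide frequencies support both counting modes and N exclusion", {
  expect_equal(dinuc_frequencies("AAAA")[["AA"]], 1)
  expect_equal(dinuc_frequencies("AAAA", overlap = FALSE)[["AA"]], 1)
  f <- dinuc_frequencies("ACGT")
  expect_equal(unname(f[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  fn <- dinuc_frequencies("ACGT", overlap = FALSE)
  expect_equal(unname(fn[c("AC", "GT")]), rep(1 / 2, 2))
  expect_equal(sum(fn > 0), 2L)
  # N-containing pairs excluded with adjusted denominator
  fN <- dinuc_frequencies("ANAA")
  expect_equal(fN[["AA"]], 1)
  expect_error(dinuc_frequencies("A"), class = "methsite_validation_error")
  expect_error(dinuc_frequencies("NNN"), class = "methsite_validation_error")
})

test_that("the correlation function is a mean squared property difference", {
  std <- standardize_properties(dinuc_property_table())
  # identical dinucleotides at both positions
  expect_equal(dinuc_correlation("AAAA", 1, 2, std), 0)
  # hand computation over the three standardized properties
  P <- as.matrix(std[c("enthalpy", "entropy", "free_energy")])
  rownames(P) <- std$dinucleotide
  expect_equal(dinuc_correlation("ACGT", 1, 2, std),
               mean((P["AC", ] - P["GT", ])^2), tolerance = 1e-12)
  expect_true(is.na(dinuc_correlation("ANGT", 1, 2, std)))
  expect_error(dinuc_correlation("ACGT", 1, 3, std),
               class = "methsite_index_error")
})

test_that("theta factors equal the brute-force double loop", {
  std <- standardize_properties(dinuc_property_table())
  for (s in random_windows(5, width = 10, seed = 21)) {
    got <- theta_factors(s, lambda = 3, properties = std)
    direct <- vapply(1:3, function(j) {
      L <- nchar(s)
      mean(vapply(seq_len(L - j - 1), function(i) {
        dinuc_correlation(s, i, j, std)
      }, numeric(1)))
    }, numeric(1))
    expect_equal(got, direct, tolerance = 1e-12)
  }
  expect_equal(theta_factors(strrep("A", 41)), rep(0, 6))
  expect_error(theta_factors("ACGT", lambda = 3),
               class = "methsite_config_error")
})

test_that("theta tiers drop N-containing terms with adjusted denominators", {
  std <- standardize_properties(dinuc_property_table())
  s <- "ACNGTACG"
  got <- theta_factors(s, lambda = 2, properties = std)
  for (j in 1:2) {
    L <- nchar(s)
    terms <- vapply(seq_len(L - j - 1), function(i) {
      dinuc_correlation(s, i, j, std)
    }, numeric(1))
    expect_equal(got[j], mean(terms, na.rm = TRUE))
  }
})

test_that("the PseDNC vector is a normalized two-block composition", {
  # poly-A: all correlation factors vanish, so d reduces to the frequencies
  v <- psednc_vector(strrep("A", 41))
  expect_length(v, 22L)
  expect_equal(unname(v[1]), 1)          # f(AA) = 1
  expect_equal(unname(v[17:22]), rep(0, 6))
  for (s in random_windows(5, seed = 31)) {
    v <- psednc_vector(s)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("increasing w shifts mass toward the correlation block", {
  s <- random_windows(1, seed = 41)
  lo <- sum(psednc_vector(s, w = 0.05)[17:22])
  hi <- sum(psednc_vector(s, w = 0.5)[17:22])
  expect_gt(hi, lo)
})

test_that("PseDNC is invariant to affine rescaling of the raw properties", {
  raw <- dinuc_property_table()
  scaled <- raw
  for (g in c("enthalpy", "entropy", "free_energy")) {
    scaled[[g]] <- -2.5 * raw[[g]] + 4
  }
  s <- random_windows(1, seed = 51)
  expect_equal(psednc_vector(s, properties = standardize_properties(scaled)),
               psednc_vector(s, properties = standardize_properties(raw)),
               tolerance = 1e-12)
})

test_that("encode_psednc returns a labeled 22-column feature frame", {
  sim <- simulate_sites(n_pos = 3, n_neg = 3, seed = 1)
  enc <- encode_psednc(sim)
  expect_equal(length(feature_cols(enc)), 22L)
  expect_equal(names(enc)[3], "psednc_f_AA")
  expect_equal(names(enc)[ncol(enc)], "psednc_theta6")
  expect_equal(unname(rowSums(enc[feature_cols(enc)])), rep(1, 6),
               tolerance = 1e-9)
  enc2 <- encode_psednc(sim, lambda = 3)
  expect_equal(length(feature_cols(enc2)), 19L)
  expect_error(encode_psednc(sim, w = 0), class = "methsite_config_error")
})
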