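test_that("RSCU follows the defining formula on constructed families", {
  counts <- stats::setNames(integer(64), names(code5$codon_to_aa))
  # 2-fold Lys family used evenly
  counts["AAA"] <- 10; counts["AAG"] <- 10
  # 6-fold Leu family with all mass on TTA
  counts["TTA"] <- 30
  cc <- structure(counts, class = "codon_counts")
  tb <- rscu(cc, code5)
  expect_equal(tb$rscu[tb$codon == "AAA"], 1)
  expect_equal(tb$rscu[tb$codon == "AAG"], 1)
  expect_equal(tb$rscu[tb$codon == "TTA"], 6)
  expect_equal(sum(tb$rscu[tb$aa == "L"]), 6)
  # unobserved families are NA, not zero
  expect_true(all(is.na(tb$rscu[tb$aa == "G"])))
})

test_that("RSCU matches the brute-force oracle and conserves family sums", {
  for (seed in 1:5) {
    cc <- random_counts(code5, lambda = 6, seed = seed)
    tb <- rscu(cc, code5)
    oracle <- oracle_rscu(cc, code5)
    expect_equal(stats::setNames(tb$rscu, tb$codon), oracle,
                 tolerance = 1e-12)
    sums <- tapply(tb$rscu, tb$aa, sum)
    sizes <- tapply(tb$family_size, tb$aa, max)
    observed <- !is.na(sums)
    expect_equal(as.numeric(sums[observed]), as.numeric(sizes[observed]),
                 tolerance = 1e-9)
  }
})

test_that("high-frequency codon sets use a strict RSCU > 1 rule", {
  uniform <- stats::setNames(integer(64), names(code5$codon_to_aa))
  uniform[code5$sense_codons] <- 5L
  hf1 <- high_frequency_codons(list(
    a = rscu(structure(uniform, class = "codon_counts"), code5)))
  expect_length(hf1$per_species$a, 0)  # all RSCU exactly 1

  biased_at <- random_counts(code5, seed = 1)
  biased_gc <- biased_at
  third <- substring(code5$sense_codons, 3, 3)
  biased_at[code5$sense_codons][third %in% c("A", "T")] <- 50L
  biased_gc[code5$sense_codons][third %in% c("G", "C")] <- 50L
  hf2 <- high_frequency_codons(list(at = rscu(biased_at, code5),
                                    gc = rscu(biased_gc, code5)))
  expect_length(hf2$shared, 0)  # disjoint preferred sets
  expect_setequal(hf2$unique$at, hf2$per_species$at)
  expect_true(all(hf2$membership$n_species == 1))
})

test_that("family homozygosity matches the hand-computed value", {
  # 2-fold family with counts (5,5): F = (10 * 0.5 - 1) / 9 = 4/9
  expect_equal(mitocub:::family_homozygosity(c(5, 5)), 4 / 9)
  # single codon observed twice: F = (2*1 - 1)/1 = 1
  expect_equal(mitocub:::family_homozygosity(c(2, 0)), 1)
  expect_true(is.na(mitocub:::family_homozygosity(c(1, 0))))
})

test_that("ENC equals the independent oracle on randomized count tables", {
  for (seed in 1:8) {
    for (code in list(code5, code1)) {
      cc <- random_counts(code, lambda = 8, seed = seed)
      expect_equal(enc(cc, code)$enc, oracle_enc(cc, code),
                   tolerance = 1e-9)
    }
  }
})

test_that("ENC reaches 20 when every family uses a single codon", {
  counts <- stats::setNames(integer(64), names(code5$codon_to_aa))
  one_per_family <- vapply(code5$families, `[`, "", 1)
  counts[one_per_family] <- 1000L
  res <- enc(structure(counts, class = "codon_counts"), code5)
  expect_equal(res$enc, 20, tolerance = 1e-9)
  expect_length(res$imputed_classes, 0)
})

test_that("uniform synonymous usage drives ENC towards the sense-codon count", {
  set.seed(11)
  for (code in list(code5, code1)) {
    n_sense <- length(code$sense_codons)
    draws <- sample(code$sense_codons, 2e5, replace = TRUE)
    counts <- stats::setNames(integer(64), names(code$codon_to_aa))
    tab <- table(draws)
    counts[names(tab)] <- as.integer(tab)
    res <- enc(structure(counts, class = "codon_counts"), code)
    expect_equal(res$enc, n_sense, tolerance = 0.5)
  }
})

test_that("scaling counts moves ENC monotonically to its infinite-n limit", {
  cc <- random_counts(code5, lambda = 4, seed = 3)
  base <- unclass(cc)
  encs <- vapply(c(1L, 4L, 16L, 64L, 256L), function(m) {
    enc(structure(base * m, class = "codon_counts"), code5)$enc
  }, numeric(1))
  # infinite-n value: F = sum(p^2) per family
  x <- base[code5$sense_codons]
  inf_F <- vapply(code5$families,
                  function(fam) sum((x[fam] / sum(x[fam]))^2), numeric(1))
  sizes <- lengths(code5$families)
  inf_enc <- sum(vapply(sort(unique(sizes)), function(k) {
    sum(sizes == k) / mean(inf_F[sizes == k])
  }, numeric(1)))
  expect_true(all(diff(abs(encs - inf_enc)) <= 1e-9))
  expect_equal(encs[5], inf_enc, tolerance = 0.05)
})

test_that("a class with no usable family is imputed from its neighbours and flagged", {
  counts <- stats::setNames(integer(64), names(code5$codon_to_aa))
  counts[unlist(code5$families[lengths(code5$families) == 2])] <- 3L
  counts[code5$families[["L"]]] <- 2L
  counts[code5$families[["S"]]] <- 2L
  # 4-fold families unobserved -> F bar imputed as mean of the 2- and 6-fold means
  res <- enc(structure(counts, class = "codon_counts"), code5)
  expect_identical(res$imputed_classes, "4")
  expect_equal(unname(res$class_means["4"]),
               mean(res$class_means[c("2", "6")]))
  expect_true(is.finite(res$enc) && res$enc > 0)
})

test_that("the expected-ENC curve evaluates exactly at anchor points", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2), "0, 1")
})

test_that("codonw-compat mode scores a table-5 count set with table-1 classes", {
  cc <- random_counts(code5, lambda = 8, seed = 21)
  compat <- enc(cc, code5, codonw_compat = TRUE)
  expect_equal(compat$enc, oracle_enc(cc, code1), tolerance = 1e-9)
  expect_identical(compat$table_id, 1L)
})
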