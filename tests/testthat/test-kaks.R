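test_that("NG86 handles the hand-derivable GGT/GGC case", {
  x <- strrep("GGT", 6)
  y <- paste0(strrep("GGT", 5), "GGC")
  e <- ng86_ka_ks(x, y)
  expect_equal(e$ka, 0)
  expect_equal(e$Sd, 1)
  expect_equal(e$S, 6)          # all third-position changes of GGT are syn
  expect_equal(e$ks, -0.75 * log(1 - (4 / 3) * (1 / 6)))

  ident <- ng86_ka_ks(x, x)
  expect_equal(ident$ka, 0)
  expect_equal(ident$ks, 0)
  expect_true(is.na(ident$omega))
})

test_that("NG86 equals brute-force path enumeration on random pairs", {
  set.seed(101)
  for (r in 1:50) {
    pr <- random_cds_pair(100)
    a <- ng86_ka_ks(pr$x, pr$y)
    b <- oracle_ng86(pr$x, pr$y)
    expect_lt(abs(a$ks - b$ks), 1e-12)
    expect_lt(abs(a$ka - b$ka), 1e-12)
    expect_equal(a$Sd, b$Sd, tolerance = 1e-12)
    expect_equal(a$N, b$N, tolerance = 1e-12)
    # symmetry
    s <- ng86_ka_ks(pr$y, pr$x)
    expect_equal(s$ks, a$ks)
    expect_equal(s$ka, a$ka)
  }
})

test_that("NG86 validates its inputs and detects saturation", {
  expect_error(ng86_ka_ks(strrep("AAA", 4), strrep("GGG", 4)), "saturation")
  expect_error(ng86_ka_ks("TAA", "TAA"), "stop")
  expect_error(ng86_ka_ks("---", "AAA"), "comparable")
  # gap codons are excluded pairwise
  e <- ng86_ka_ks("GGT---GGT", "GGTGGAGGC")
  expect_equal(e$n_codons, 2L)
})

test_that("codon back-translation expands protein gaps to triplet gaps", {
  prot <- c(a = "MKV", b = "MKV")
  cds <- c(a = "ATGAAAGTT", b = "ATGAAGGTA")
  ca <- codon_align(prot, cds)
  expect_equal(unname(ca["a"]), "ATGAAAGTT")

  prot2 <- c(a = "MK-V", b = "MKLV")
  cds2 <- c(a = "ATGAAAGTT", b = "ATGAAGTTAGTA")
  ca2 <- codon_align(prot2, cds2)
  expect_equal(unname(ca2["a"]), "ATGAAA---GTT")
  expect_equal(nchar(ca2[["b"]]), 12L)

  expect_error(codon_align(c(a = "MK"), c(a = "ATGTAAAAA")), "stop")
  expect_error(codon_align(c(a = "MKV"), c(a = "ATGAAAAAA")),
               "back-translation")
})

test_that("block Ks summaries apply the saturation filter", {
  b <- block_ks(c(0.2, 0.2, 0.2))
  expect_equal(b$mean_ks, 0.2)
  expect_equal(b$sd_ks, 0)
  b2 <- block_ks(c(0.2, 1.5), cutoff = 1.0)
  expect_equal(b2$mean_ks, 0.2)
  expect_equal(b2$n_retained, 1L)
  b3 <- block_ks(c(1.5, 2), cutoff = 1.0)
  expect_true(b3$all_removed)
})

test_that("molecular-clock dating reproduces published block ages", {
  expect_equal(date_duplication(0.60, 6.1e-9, rounded = TRUE), 49)
  expect_equal(date_duplication(0.17, 6.1e-9, rounded = TRUE), 14)
  expect_equal(date_duplication(0, 6.1e-9), 0)
  expect_error(date_duplication(0.5, 0), "lambda")

  tab <- read.delim(system.file("extdata",
                                "soybean_wrky_segmental_blocks.tsv",
                                package = "famevol"))
  expect_gt(nrow(tab), 80)
  t_est <- date_duplication(tab$ks_mean, lambda = 6.1e-9, rounded = TRUE)
  expect_identical(as.integer(t_est), as.integer(tab$time_mya))
  # linearity in Ks
  expect_equal(date_duplication(2 * tab$ks_mean, 6.1e-9),
               2 * date_duplication(tab$ks_mean, 6.1e-9))
})
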