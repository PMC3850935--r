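test_that("element counting matches planted copies and validates input", {
  cat_ <- load_cis_catalog()
  expect_true(all(c("G-box", "Box4", "ABRE") %in% cat_$element))

  sp <- sim_promoters(1, 200,
                      elements = list(list(pattern = "CACGTG", copies = 2)),
                      background = c(A = .5, T = .5), seed = 2)
  sc <- scan_cis_elements(sp$promoters, cat_)
  expect_equal(unname(sc$counts[1, "G-box"]), 2L)
  # planted copies sit verbatim at the recorded offsets
  for (k in seq_len(nrow(sp$truth)))
    expect_equal(substr(sp$promoters[[sp$truth$promoter[k]]],
                        sp$truth$offset[k], sp$truth$offset[k] + 5),
                 "CACGTG")

  empty <- scan_cis_elements(sp$promoters,
                             data.frame(element = character(0),
                                        pattern = character(0)))
  expect_equal(ncol(empty$counts), 0L)

  expect_error(scan_cis_elements(c(p = "ACGTQX"), cat_), "position 5")
  expect_error(sim_promoters(1, 10, elements = list(
    list(pattern = strrep("A", 8), copies = 2))), "exceeds")
})

test_that("background without the pattern alphabet yields exact counts", {
  sp <- sim_promoters(20, 300,
                      elements = list(list(pattern = "GGGGGCCCCC",
                                           copies = 3)),
                      background = c(A = .5, T = .5), seed = 3)
  cnt <- scan_cis_elements(sp$promoters,
                           data.frame(element = "el",
                                      pattern = "GGGGGCCCCC"))
  expect_equal(mean(cnt$counts), 3)

  none <- sim_promoters(5, 200, background = c(A = .5, T = .5), seed = 4)
  cnt0 <- scan_cis_elements(none$promoters,
                            data.frame(element = "G-box",
                                       pattern = "CACGTG"))
  expect_true(all(cnt0$counts == 0))
})

test_that("IUPAC scanning equals the brute-force position matcher", {
  set.seed(8)
  pats <- c("CACGTG", "ACGT", "TTGACY", "MACGYG", "GNGC")
  for (r in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
    for (p in pats) {
      expect_equal(famevol:::count_pattern(s, p, "both"),
                   oracle_iupac_count(s, p, both_strands = TRUE),
                   info = paste(p, "both"))
      expect_equal(famevol:::count_pattern(s, p, "forward"),
                   oracle_iupac_count(s, p, both_strands = FALSE),
                   info = paste(p, "forward"))
    }
  }
})

test_that("per-group means aggregate counts", {
  proms <- c(g1 = "TTCACGTGTT", g2 = "TTTTTTTTTT", g3 = "CACGTGCACGTG")
  sc <- scan_cis_elements(proms, data.frame(element = "G-box",
                                            pattern = "CACGTG"),
                          groups = c("A", "A", "B"))
  expect_equal(unname(sc$group_means["A", "G-box"]), 0.5)
  expect_equal(unname(sc$group_means["B", "G-box"]), 2)
})
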