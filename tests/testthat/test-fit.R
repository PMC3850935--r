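test_that("single-ratio fits recover simulation parameters", {
  tr <- sim_tree(6, "birth_death", seed = 10)
  s <- sim_codon_alignment(tr, 300, regime_m0(0.3), kappa = 2, seed = 12)
  f <- fit_codon_model(s, tr, "M0", n_starts = 2)
  expect_s3_class(f, "codon_fit")
  expect_true(f$converged)
  expect_lt(abs(f$params$omega - 0.3), 0.15)
  expect_lt(abs(f$kappa - 2), 1)
  expect_named(coef(f), c("kappa", "omega"))
  expect_equal(attr(logLik(f), "df"), 2)
  expect_output(print(f), "M0")
})

test_that("model nesting holds at the optimum", {
  tr <- sim_tree(5, "birth_death", seed = 3)
  s <- sim_codon_alignment(tr, 150, regime_discrete(c(0.7, 0.3),
                                                    c(0.05, 0.6)),
                           seed = 4)
  f0 <- fit_codon_model(s, tr, "M0", n_starts = 1)
  f3 <- fit_codon_model(s, tr, "M3", K = 3, n_starts = 1)
  expect_gte(f3$logLik, f0$logLik - 1e-4)

  f7 <- fit_codon_model(s, tr, "M7", ncat = 5, n_starts = 1)
  f8 <- fit_codon_model(s, tr, "M8", ncat = 5, n_starts = 1)
  expect_gte(f8$logLik, f7$logLik - 1e-4)

  lr <- codon_lrt(f7, f8)
  expect_equal(lr$df, 2)
  expect_gte(lr$two_delta_lnL, 0)
  expect_error(codon_lrt(f0, f8), "non-nested")
})

test_that("the M7/M8 test does not reject its own null", {
  tr <- sim_tree(6, "birth_death", seed = 8)
  sig <- vapply(1:5, function(r) {
    om <- qbeta((1:5 - 0.5) / 5, 0.5, 1.5)   # a beta-shaped omega mixture
    s <- sim_codon_alignment(tr, 100, regime_discrete(rep(0.2, 5), om),
                             seed = 500 + r)
    f7 <- fit_codon_model(s, tr, "M7", ncat = 4, n_starts = 1,
                          control = list(factr = 1e8))
    f8 <- fit_codon_model(s, tr, "M8", ncat = 4, n_starts = 1,
                          control = list(factr = 1e8))
    codon_lrt(f7, f8)$p_value < 0.01
  }, TRUE)
  expect_lte(sum(sig), 1)
})

test_that("likelihood-ratio arithmetic matches the chi-squared reference", {
  f_null <- structure(list(model = "M0", null = FALSE, logLik = -100,
                           nfree = 2), class = "codon_fit")
  f_alt <- structure(list(model = "M3", null = FALSE, logLik = -100,
                          nfree = 6), class = "codon_fit")
  lr <- codon_lrt(f_null, f_alt)
  expect_equal(lr$two_delta_lnL, 0)
  expect_equal(lr$p_value, 1)

  # a 2dlnL of 335.95 on 4 df is overwhelming evidence
  f_alt$logLik <- -100 + 335.95 / 2
  lr2 <- codon_lrt(f_null, f_alt)
  expect_equal(lr2$two_delta_lnL, 335.95)
  expect_lt(lr2$p_value, 0.01)
})

test_that("site posteriors flag simulated positively selected sites", {
  tr <- sim_tree(8, "birth_death", seed = 5)
  fg <- c("t1", "t2", "t3")
  reg <- regime_branch_site(0.6, 0.2, omega0 = 0.1, omega2 = 5,
                            foreground = fg)
  s <- sim_codon_alignment(tr, 300, reg, seed = 77)
  fa <- fit_codon_model(s, tr, "bsA", foreground = fg, n_starts = 1)
  for (method in c("NEB", "BEB")) {
    pp <- site_posteriors(fa, method)
    sel <- s$site_class %in% c("2a", "2b")
    expect_gt(mean(pp$prob[sel]), mean(pp$prob[!sel]))
    expect_true(all(pp$prob >= 0 & pp$prob <= 1))
    expect_true(all(pp$star[pp$prob > 0.99] == "**"))
  }

  f0 <- fit_codon_model(s, tr, "bsA", null = TRUE, foreground = fg,
                        n_starts = 1)
  expect_error(site_posteriors(f0), "no positively selected class")

  f7 <- fit_codon_model(s, tr, "M7", ncat = 4, n_starts = 1)
  expect_error(site_posteriors(f7), "no positively selected class")
})

test_that("degenerate single-class fits give unit posteriors", {
  tr <- sim_tree(4, "balanced", seed = 2)
  s <- sim_codon_alignment(tr, 60, regime_m0(2), kappa = 2, seed = 3)
  f <- fit_codon_model(s, tr, "M3", K = 1, n_starts = 1)
  if (f$params$omega > 1) {
    pp <- site_posteriors(f, "NEB")
    expect_true(all(pp$prob == 1))
  } else {
    expect_error(site_posteriors(f, "NEB"), "no positively selected")
  }
})
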