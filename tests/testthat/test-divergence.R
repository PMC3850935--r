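star4 <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")

test_that("Fitch counts follow minimum-change logic", {
  aln <- c(a = "ARK", b = "ARK", c = "ARK", d = "AKK")
  counts <- site_substitution_counts(aln, star4, c("a", "b", "c", "d"))
  expect_equal(counts, c(0L, 1L, 0L))
  expect_error(site_substitution_counts(aln, star4, c("a", "b")), ">= 3")
})

test_that("Fitch counts equal exhaustive minimisation on small trees", {
  set.seed(5)
  for (r in 1:20) {
    n <- sample(3:6, 1)
    tr <- sim_tree(n, sample(c("balanced", "caterpillar", "birth_death"),
                             1), seed = r)
    states <- sample(c("A", "R", "K", "D"), n, replace = TRUE)
    aln <- setNames(states, tr$tip.label)
    impl <- site_substitution_counts(setNames(states, tr$tip.label), tr,
                                     tr$tip.label)
    oracle <- oracle_fitch(setNames(states, tr$tip.label), tr)
    expect_equal(impl, oracle)
  }
})

test_that("theta-I estimation respects the no-divergence limit", {
  set.seed(2)
  l <- rgamma(300, 0.7, 0.7)
  x <- rpois(300, 2.5 * l)
  fit <- estimate_theta1(list(x1 = x, x2 = x, d1 = NULL, d2 = NULL))
  expect_s3_class(fit, "theta_fit")
  expect_lt(fit$theta, 0.15)
  expect_gt(fit$p_value, 0.05)
  expect_gte(fit$lnL_alt, fit$lnL_null - 1e-6)

  # degenerate all-zero counts
  fit0 <- estimate_theta1(list(x1 = rep(0L, 50), x2 = rep(0L, 50),
                               d1 = NULL, d2 = NULL))
  expect_equal(fit0$theta, 0)
  expect_true(fit0$degenerate)
})

test_that("theta-I is recovered from model simulations", {
  est <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 200; theta <- 0.4; alpha <- 0.5
    ind <- runif(n) < theta
    l1 <- rgamma(n, alpha, alpha)
    l2 <- ifelse(ind, rgamma(n, alpha, alpha), l1)
    x1 <- rpois(n, 2 * l1); x2 <- rpois(n, 2.5 * l2)
    estimate_theta1(list(x1 = x1, x2 = x2, d1 = NULL, d2 = NULL))$theta
  }, 0)
  expect_lt(abs(mean(est) - 0.4), 0.15)
})

test_that("theta-II count-category model behaves at its edges", {
  cl <- load_aa_classes()
  mk_aln <- function(cons1, cons2, reps = 3) {
    c(setNames(rep(paste(cons1, collapse = ""), reps), paste0("x", 1:reps)),
      setNames(rep(paste(cons2, collapse = ""), reps), paste0("y", 1:reps)))
  }
  cons <- strsplit("ARKDELMNPQ", "")[[1]]
  pair_same <- list(aln = mk_aln(cons, cons), cluster1 = paste0("x", 1:3),
                    cluster2 = paste0("y", 1:3))
  f_same <- estimate_theta2(pair_same, cl)
  expect_equal(f_same$theta, 0)
  expect_equal(f_same$p_value, 1)

  # single property class: no radical difference is definable
  one_class <- setNames(rep("all", length(cl)), names(cl))
  cons2 <- cons; cons2[2] <- "D"
  pair_diff <- list(aln = mk_aln(cons, cons2), cluster1 = paste0("x", 1:3),
                    cluster2 = paste0("y", 1:3))
  f_one <- estimate_theta2(pair_diff, one_class)
  expect_equal(f_one$theta, 0)
  expect_true(f_one$degenerate)
})

test_that("planted radical fixed differences yield significant theta-II", {
  cl <- load_aa_classes()
  sig <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 150
    c1 <- sample(names(cl), n, replace = TRUE)
    c2 <- c1
    div <- sample(n, round(0.2 * n))
    for (i in div) c2[i] <- sample(names(cl)[cl != cl[[c1[i]]]], 1)
    mk <- function(cons) vapply(1:4, function(k) {
      v <- cons
      j <- sample(n, 5)
      v[j] <- sample(names(cl), 5, replace = TRUE)
      paste(v, collapse = "")
    }, "")
    aln <- c(setNames(mk(c1), paste0("x", 1:4)),
             setNames(mk(c2), paste0("y", 1:4)))
    estimate_theta2(list(aln = aln, cluster1 = paste0("x", 1:4),
                         cluster2 = paste0("y", 1:4)), cl)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(sig), 0.8)
})

test_that("site posteriors Qk flag the divergent state", {
  set.seed(9)
  n <- 200; theta <- 0.5; alpha <- 0.5
  ind <- runif(n) < theta
  l1 <- rgamma(n, alpha, alpha)
  l2 <- ifelse(ind, rgamma(n, alpha, alpha), l1)
  x1 <- rpois(n, 3 * l1); x2 <- rpois(n, 3 * l2)
  fit <- estimate_theta1(list(x1 = x1, x2 = x2, d1 = NULL, d2 = NULL))
  qk <- site_qk(fit)
  expect_true(all(qk$qk >= 0 & qk$qk <= 1))
  expect_gt(mean(qk$qk[ind]), mean(qk$qk[!ind]))
  expect_false(any(site_qk(fit, cutoff = 1.01)$flagged))

  # theta = 0 means zero posterior mass on divergence
  fit0 <- estimate_theta1(list(x1 = rep(0L, 50), x2 = rep(0L, 50),
                               d1 = NULL, d2 = NULL))
  expect_true(all(site_qk(fit0)$qk == 0))
})

test_that("cluster pairs drive theta estimation from alignments", {
  tr <- sim_tree(8, "balanced", seed = 6, mean_brlen = 0.3)
  s <- sim_codon_alignment(tr, 150, regime_m0(0.8), seed = 13)
  prots <- vapply(s$alignment, famevol:::translate_cds, "")
  cp <- cluster_pair(prots, tr, paste0("t", 1:4), paste0("t", 5:8))
  expect_s3_class(cp, "cluster_pair")
  expect_length(cp$x1, 150)
  fit <- estimate_theta1(cp)
  expect_true(fit$theta >= 0 && fit$theta < 1)
  expect_error(cluster_pair(prots, tr, paste0("t", 1:4), paste0("t", 4:8)),
               "disjoint")
})
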