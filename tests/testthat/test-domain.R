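make_domain <- function(x1 = 4, x2 = 22, tail = "H", gap = 6) {
  paste0("WRKYGQK", strrep("A", gap), "C", strrep("L", x1), "C",
         strrep("S", x2), "H", "A", tail)
}

test_that("domain scanning follows the spacing rules", {
  p <- paste0("MEEE", make_domain(4, 22, "H"), "DDD")
  h <- scan_wrky_domains(p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$finger_type, "C2H2")
  expect_equal(h$hepta_start, 4L)

  # C-X6-C spacing matches neither finger type
  bad <- paste0("MEEE", make_domain(6, 22, "H"), "DDD")
  expect_equal(nrow(scan_wrky_domains(bad)), 0L)

  # C-X7-C-X23-H-X-C is the group III finger
  g3 <- paste0("MEEE", make_domain(7, 23, "C"), "DDD")
  h3 <- scan_wrky_domains(g3)
  expect_equal(h3$finger_type, "C2HC")

  two <- paste0("M", make_domain(), strrep("G", 10), make_domain(5, 23, "H"))
  h2 <- scan_wrky_domains(two)
  expect_equal(nrow(h2), 2L)
  expect_true(all(diff(h2$hepta_start) > 0))
  expect_true(all(h2$finger_start > h2$hepta_start))
})

test_that("domain scan agrees with brute-force index enumeration", {
  set.seed(42)
  pat <- domain_pattern()
  for (r in 1:50) {
    p <- random_protein(200)
    # plant a domain in half the cases so hits actually occur
    if (r %% 2 == 0) {
      at <- sample(1:120, 1)
      substr(p, at, at + 43) <- make_domain(4, 22, "H")
    }
    hits <- scan_wrky_domains(p, pat)
    bf <- oracle_domain_pairs(p, pat$max_gap)
    # every reported hit must be a genuine (hepta, finger) pair
    if (nrow(hits)) {
      expect_true(all((hits$hepta_start + 1) %in% bf$hepta))
      expect_true(all((hits$finger_start + 1) %in% bf$fingers[, 1]))
    }
    # a hit must exist iff some hepta has a finger within the gap
    any_pair <- FALSE
    if (length(bf$hepta) && !is.null(bf$fingers)) {
      for (h in bf$hepta)
        if (any(bf$fingers[, 1] >= h + 7 &
                bf$fingers[, 1] - (h + 7) <= pat$max_gap)) any_pair <- TRUE
    }
    expect_equal(nrow(hits) > 0, any_pair)
  }
})

test_that("group classification follows domain number and finger type", {
  two_c2h2 <- scan_wrky_domains(paste0("M", make_domain(), strrep("G", 8),
                                       make_domain()))
  cg <- classify_group(two_c2h2)
  expect_equal(cg$group, "I")
  expect_equal(cg$domain_labels, c("N", "C"))
  expect_false(cg$flagged)

  one_c2hc <- scan_wrky_domains(paste0("M", make_domain(7, 23, "C")))
  expect_equal(classify_group(one_c2hc)$group, "III")

  one_c2h2 <- scan_wrky_domains(paste0("M", make_domain()))
  expect_equal(classify_group(one_c2h2)$group, "II")

  expect_equal(classify_group(scan_wrky_domains("MAAAA"))$group,
               "unassigned")

  mixed <- scan_wrky_domains(paste0("M", make_domain(), strrep("G", 8),
                                    make_domain(7, 23, "C")))
  cgm <- classify_group(mixed)
  expect_equal(cgm$group, "I")
  expect_true(cgm$flagged)
})

test_that("similarity prescreen behaves like a local-alignment screen", {
  refs <- load_subgroup_refs()$sequence
  r <- prescreen_similarity(refs[1], refs)
  expect_true(r$pass)
  self_raw <- famevol:::sw_scores(refs[1], refs[1])
  expect_equal(r$raw_score, self_raw)

  expect_false(prescreen_similarity(strrep("A", 80), refs)$pass)
  expect_error(prescreen_similarity("MAA", character(0)), "non-empty")

  # reference embedded verbatim in a long decoy keeps its self-score
  set.seed(7)
  decoy <- random_protein(500, alphabet = c("D", "E", "N", "Q", "T"))
  at <- 101
  emb <- paste0(substr(decoy, 1, at - 1), refs[2],
                substr(decoy, at, 500 - nchar(refs[2])))
  r2 <- prescreen_similarity(emb, refs[2])
  expect_true(r2$pass)
  expect_equal(r2$raw_score, famevol:::sw_scores(refs[2], refs[2]))
})

test_that("subgroup assignment picks the nearest labelled reference", {
  refs <- load_subgroup_refs()
  q <- refs$sequence[refs$subgroup == "IIa"][1]
  expect_equal(assign_subgroup(q, refs)$subgroup, "IIa")

  # exact tie between a IIa and a IIb reference breaks to IIa
  tie_refs <- data.frame(id = c("a", "b", "c", "d", "e"),
                         subgroup = paste0("II", letters[1:5]),
                         sequence = c(q, q, refs$sequence[7],
                                      refs$sequence[10], refs$sequence[13]))
  expect_equal(assign_subgroup(q, tie_refs)$subgroup, "IIa")

  expect_error(assign_subgroup(q, refs[refs$subgroup != "IIe", ]),
               "missing")

  set.seed(11)
  pool <- c("A", "D", "E", "G", "K", "L", "N", "P", "Q", "R", "S", "T",
            "V", "Y", "I", "F", "M")
  hits <- replicate(100, {
    base <- refs$sequence[refs$subgroup == "IIc"][sample(3, 1)]
    v <- strsplit(base, "")[[1]]
    pos <- sample(seq_along(v), round(0.1 * length(v)))
    v[pos] <- sample(pool, length(pos), replace = TRUE)
    assign_subgroup(paste(v, collapse = ""), refs)$subgroup == "IIc"
  })
  expect_gte(mean(hits), 0.90)
})

test_that("neighbor joining recovers additive and simulated topologies", {
  expect_error(build_nj_tree(c(a = "AA", b = "AA")), ">= 3")

  # four sequences whose p-distances are exactly additive on ((a,b),(c,d))
  seqs <- c(a = paste0(strrep("A", 16), "RR", "KK"),
            b = paste0(strrep("A", 16), "RR", "EE"),
            c = paste0(strrep("C", 16), "RR", "KK"),
            d = paste0(strrep("C", 16), "DD", "KK"))
  tr <- build_nj_tree(seqs)
  exp_tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(exp_tr)), 0,
               ignore_attr = TRUE)

  ident <- build_nj_tree(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  expect_true(all(ident$edge.length == 0))

  # protein alignment simulated on a known tree at low divergence
  gen <- sim_tree(8, "birth_death", seed = 3, mean_brlen = 0.08)
  s <- sim_codon_alignment(gen, 400, regime_m0(1), seed = 6)
  prots <- vapply(s$alignment, famevol:::translate_cds, "")
  nj <- build_nj_tree(prots)
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
})
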