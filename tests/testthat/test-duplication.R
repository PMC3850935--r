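toy_genes <- function(ordinals, chrom = "chr1", spacing = 10000L) {
  n <- length(ordinals)
  data.frame(id = paste0("g", ordinals), chrom = chrom, ordinal = ordinals,
             start = 1L + ordinals * spacing,
             end = 1000L + ordinals * spacing,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("tandem clustering applies the intervening-gene rule", {
  g <- toy_genes(0:20)
  td <- find_tandem(g, c("g5", "g9"), max_intervening = 10)
  expect_equal(sort(td$id), c("g5", "g9"))
  expect_equal(td$max_gap[1], 3L)

  td2 <- find_tandem(g, c("g5", "g17"), max_intervening = 10)
  expect_equal(nrow(td2), 0L)

  # 11 intervening genes exactly at the boundary
  td3 <- find_tandem(g, c("g5", "g16"), max_intervening = 10)
  expect_equal(nrow(td3), 2L)

  expect_error(find_tandem(g, "missing_gene"), "absent")
})

test_that("best non-self matches are mutual for identical pairs", {
  set.seed(3)
  a <- random_protein(80)
  prots <- c(A = a, B = a, C = random_protein(80, alphabet = c("D", "E",
                                                              "N", "T")))
  bm <- best_nonself_matches(prots)
  expect_equal(unname(bm["A"]), "B")
  expect_equal(unname(bm["B"]), "A")
  expect_true(is.na(bm["C"]))

  low <- c(X = random_protein(60, alphabet = c("A", "G")),
           Y = random_protein(60, alphabet = c("D", "E")))
  expect_true(all(is.na(best_nonself_matches(low))))
})

test_that("segmental detection needs enough anchors inside the window", {
  # two chromosomes; genes 0..9 on each; focal g0 ~ paralog h0 with anchors
  g1 <- toy_genes(0:9, "chr1")
  g2 <- toy_genes(0:9, "chr2")
  g2$id <- sub("^g", "h", g2$id)
  genes <- rbind(g1, g2)
  bm <- setNames(c("h1", "h2", "h3", "g1", "g2", "g3"),
                 c("g1", "g2", "g3", "h1", "h2", "h3"))
  b <- find_segmental("g0", "h0", genes, bm, window_kb = 100,
                      min_anchors = 3)
  expect_equal(b$n_anchors, 3L)
  expect_setequal(b$anchors$gene, c("g1", "g2", "g3"))

  expect_null(find_segmental("g0", "h0", genes, bm, min_anchors = 4))
  expect_null(find_segmental("g0", "h0", genes,
                             setNames(character(0), character(0)),
                             min_anchors = 1))

  # anchors placed outside the 100-kb window do not count
  far <- genes
  far$start[far$id %in% c("g1", "g2", "g3")] <-
    far$start[far$id %in% c("g1", "g2", "g3")] + 150000L
  far$end <- far$start + 999L
  expect_null(find_segmental("g0", "h0", far, bm, min_anchors = 1))
})

test_that("origin classification is exhaustive and consistent", {
  tand <- data.frame(cluster = 1L, chrom = "chr1", id = c("a", "b"),
                     max_gap = 0L)
  blocks <- list(list(focal = "b", paralog = "c",
                      anchors = data.frame(gene = "x", match = "y"),
                      n_anchors = 1L, window_kb = 100))
  or <- classify_origin(c("a", "b", "c", "d"), tand, blocks)
  expect_equal(or$origin, c("tandem", "both", "segmental", "dispersed"))
  os <- origin_summary(or)
  expect_equal(unname(os$counts["segmental"]), 2)
  expect_equal(unname(os$percent["segmental"]), 50.0)
  expect_equal(sum(or$origin == "dispersed") +
                 sum(or$tandem | or$segmental), nrow(or))
})

test_that("summary percentages reproduce the reference arithmetic", {
  origin <- data.frame(
    gene = sprintf("w%03d", 1:133),
    tandem = rep(c(TRUE, FALSE), c(18, 115)),
    segmental = rep(c(FALSE, TRUE), c(31, 102)))
  origin$origin <- ifelse(origin$tandem & origin$segmental, "both",
                   ifelse(origin$tandem, "tandem",
                   ifelse(origin$segmental, "segmental", "dispersed")))
  os <- origin_summary(origin)
  expect_equal(unname(os$percent["segmental"]), 76.7)
  expect_equal(unname(os$percent["tandem"]), 13.5)
})
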