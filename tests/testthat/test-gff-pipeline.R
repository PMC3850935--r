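minimal_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\tCDS\t1001\t1300\t.\t+\t0\tID=gA.c1;Parent=gA.t1",
    "chr1\tsrc\tCDS\t1501\t2000\t.\t+\t0\tID=gA.c2;Parent=gA.t1",
    "chr1\tsrc\tgene\t100\t400\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t100\t400\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\tCDS\t100\t400\t.\t-\t0\tID=gB.c1;Parent=gB.t1"),
    path)
  path
}

test_that("GFF3 parsing preserves coordinates and orders ordinals by start", {
  f <- withr::local_tempfile(fileext = ".gff3")
  minimal_gff(f)
  g <- parse_gff3(f)
  expect_equal(nrow(g), 2L)
  # gB comes first on the chromosome although it is second in the file
  expect_equal(g$ordinal[g$id == "gB"], 0L)
  expect_equal(g$ordinal[g$id == "gA"], 1L)
  expect_equal(g$start[g$id == "gA"], 1001L)
  expect_equal(g$end[g$id == "gA"], 2000L)
  expect_equal(g$n_exons[g$id == "gA"], 2L)
  expect_equal(g$cds_len[g$id == "gA"], 800L)
  expect_equal(g$n_exons[g$id == "gB"], 1L)

  st <- summarize_gene_structure(g)
  expect_equal(st$n_exons[st$id == "gA"], 2L)
})

test_that("malformed GFF3 lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=x",
               "chr1\tgene\tbroken line"), f)
  expect_error(parse_gff3(f), "line 3")
})

test_that("the pipeline validates stage inputs before any work", {
  cfg <- pipeline_config(gff = "/nonexistent.gff3", cds = NULL,
                         proteins = NULL, family = NULL)
  expect_error(run_pipeline(cfg, stages = "classify"), "requires")
  expect_error(run_pipeline(cfg, stages = "dup"), "requires")
  expect_error(pipeline_config(lambda = -1), "positive")
})

test_that("an empty family list yields empty but valid reports", {
  sim <- sim_genome(genome_layout(1, 8, family_fraction = 0), seed = 2)
  d <- withr::local_tempdir()
  write_genome(sim, d)
  cfg <- pipeline_config(gff = file.path(d, "genome.gff3"),
                         cds = file.path(d, "cds.fasta"),
                         proteins = file.path(d, "proteins.fasta"),
                         family = file.path(d, "family.tsv"))
  res <- run_pipeline(cfg, stages = c("classify", "dup", "date"))
  expect_equal(nrow(res$origin), 0L)
  expect_equal(nrow(res$dates), 0L)
  expect_equal(res$summary$family_size, 0L)
})

test_that("pipeline reruns are reproducible and summaries are exact", {
  lay <- genome_layout(2, 24,
    segmental = list(list(src_chrom = 1, src_index = 2, dst_chrom = 2,
                          dst_index = 8, n_anchors = 3, target_ks = 0.2)),
    family_fraction = 0)
  sim <- sim_genome(lay, seed = 21)
  d <- withr::local_tempdir()
  write_genome(sim, d)
  cfg <- pipeline_config(gff = file.path(d, "genome.gff3"),
                         cds = file.path(d, "cds.fasta"),
                         proteins = file.path(d, "proteins.fasta"),
                         family = file.path(d, "family.tsv"))
  r1 <- run_pipeline(cfg, stages = c("classify", "dup", "date"))
  r2 <- run_pipeline(cfg, stages = c("classify", "dup", "date"))
  expect_identical(r1$dates, r2$dates)
  expect_identical(r1$origin, r2$origin)

  expect_equal(nrow(r1$dates), 1L)
  expect_lt(abs(r1$dates$mean_ks - 0.2), 0.05)
  expect_equal(r1$summary$family_size, length(sim$family_ids))
  expect_equal(unname(r1$summary$origin_percent["segmental"]),
               round(100 * sum(r1$origin$segmental) /
                       nrow(r1$origin), 1))
})
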