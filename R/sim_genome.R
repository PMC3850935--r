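# Synthetic genome layouts with planted tandem arrays and segmental blocks,
# emitted as GFF3 + CDS/protein FASTA + a ground-truth table, so the
# duplication classifier and the Ks clock can be validated end to end.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# Codons per amino acid (sense codons only), for reverse translation.
codons_for_aa <- function() {
  if (!is.null(.famevol$cod_by_aa)) return(.famevol$cod_by_aa)
  cs <- codon_states()
  .famevol$cod_by_aa <- split(cs$codons, cs$aa)
  .famevol$cod_by_aa
}

reverse_translate <- function(protein) {
  by_aa <- codons_for_aa()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue: ", a)
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
}

#' Random WRKY-like protein sequence
#'
#' Draws a protein carrying the canonical domain architecture of the
#' requested group: group I has an N- and a C-terminal WRKYGQK+C2H2 domain,
#' group II a single C2H2 domain, group III a single C2HC domain.
#'
#' @param group `"I"`, `"II"` or `"III"`.
#' @param flank number of random flanking residues on each side.
#' @return protein string (uses the current RNG stream).
#' @export
random_wrky_protein <- function(group = c("II", "I", "III"), flank = 15) {
  group <- match.arg(group)
  rnd <- function(n) paste(sample(setdiff(AA20, c("C", "H", "W")), n,
                                  replace = TRUE), collapse = "")
  dom <- function(type) {
    if (type == "C2H2")
      paste0("WRKYGQK", rnd(6), "C", rnd(4), "C", rnd(22), "H", rnd(1), "H")
    else
      paste0("WRKYGQK", rnd(6), "C", rnd(7), "C", rnd(23), "H", rnd(1), "C")
  }
  switch(group,
    I = paste0(rnd(flank), dom("C2H2"), rnd(12), dom("C2H2"), rnd(flank)),
    II = paste0(rnd(flank), dom("C2H2"), rnd(flank)),
    III = paste0(rnd(flank), dom("C2HC"), rnd(flank)))
}

random_background_protein <- function(n_aa) {
  paste0("M", paste(sample(AA20, n_aa - 1, replace = TRUE), collapse = ""))
}

#' Genome layout specification for the synthetic generator
#'
#' @param n_chromosomes,genes_per_chromosome genome dimensions.
#' @param tandem list of planted tandem arrays, each
#'   `list(chrom =, start =, size =, intervening =)` with `start` a 0-based
#'   ordinal and `intervening` the number of background genes between
#'   consecutive members (recoverable arrays need `intervening <= 10`).
#' @param segmental list of planted blocks, each
#'   `list(src_chrom =, src_index =, dst_chrom =, dst_index =, n_anchors =,
#'   target_ks =)`; the focal family gene sits at `src_index` and its
#'   `n_anchors` following background genes are the anchors.
#' @param family_fraction fraction of genes carrying the family domain
#'   (extras beyond the planted ones, placed well apart).
#' @return validated layout object.
#' @export
genome_layout <- function(n_chromosomes = 3, genes_per_chromosome = 30,
                          tandem = list(), segmental = list(),
                          family_fraction = 0.05) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 1,
            family_fraction >= 0, family_fraction <= 1)
  for (td in tandem) {
    stopifnot(td$size >= 2, td$intervening >= 0)
    span <- td$start + (td$size - 1) * (td$intervening + 1)
    if (td$chrom > n_chromosomes || span >= genes_per_chromosome)
      stop("planted tandem array exceeds chromosome capacity")
  }
  for (sg in segmental) {
    stopifnot(sg$n_anchors >= 1, sg$target_ks >= 0)
    if (sg$src_chrom > n_chromosomes || sg$dst_chrom > n_chromosomes ||
        sg$src_index + sg$n_anchors >= genes_per_chromosome ||
        sg$dst_index + sg$n_anchors >= genes_per_chromosome)
      stop("planted segmental block exceeds chromosome capacity")
  }
  structure(list(n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 tandem = tandem, segmental = segmental,
                 family_fraction = family_fraction),
            class = "genome_layout")
}

#' Simulate a genome layout with planted duplications
#'
#' Generates gene models laid out on chromosomes (non-overlapping, sorted
#' coordinates, 1--4 CDS segments per gene), plants the requested tandem
#' arrays (cluster members are recent copies of one family gene) and
#' segmental blocks (the focal gene and its flanking anchors are copied to
#' the target location and evolved to the requested Ks with
#' [evolve_pair_to_ks()]), and returns everything the downstream pipeline
#' consumes together with a ground-truth table.
#'
#' @param layout a [genome_layout()].
#' @param seed integer seed; output is a pure function of (layout, seed).
#' @return list with `genes` (data.frame: id, chrom, ordinal, start, end,
#'   strand, n_exons, cds_len), `cds`, `proteins` (named vectors),
#'   `family_ids`, `gff` (GFF3 text lines), and `truth`
#'   (list of `tandem` and `segmental` data.frames).
#' @export
sim_genome <- function(layout, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  with_seed(seed, {
    nch <- layout$n_chromosomes
    gpc <- layout$genes_per_chromosome
    ng <- nch * gpc
    gene_key <- function(ch, i) sprintf("g%02dx%03d", ch, i)

    # role bookkeeping: which (chrom, ordinal) slots are special
    role <- matrix("bg", nch, gpc)
    tandem_truth <- NULL
    seg_truth <- NULL
    fam_slots <- NULL
    for (ti in seq_along(layout$tandem)) {
      td <- layout$tandem[[ti]]
      ords <- td$start + (0:(td$size - 1)) * (td$intervening + 1)
      if (any(role[td$chrom, ords + 1] != "bg"))
        stop("planted features overlap")
      role[td$chrom, ords + 1] <- paste0("tandem", ti)
      fam_slots <- rbind(fam_slots, cbind(td$chrom, ords))
      tandem_truth <- rbind(tandem_truth, data.frame(
        event = paste0("tandem", ti), chrom = paste0("chr", td$chrom),
        id = gene_key(td$chrom, ords), intervening = td$intervening,
        stringsAsFactors = FALSE))
    }
    for (si in seq_along(layout$segmental)) {
      sg <- layout$segmental[[si]]
      src <- sg$src_index + 0:sg$n_anchors
      dst <- sg$dst_index + 0:sg$n_anchors
      if (any(role[sg$src_chrom, src + 1] != "bg") ||
          any(role[sg$dst_chrom, dst + 1] != "bg"))
        stop("planted features overlap")
      role[sg$src_chrom, src + 1] <- paste0("segsrc", si)
      role[sg$dst_chrom, dst + 1] <- paste0("segdst", si)
      fam_slots <- rbind(fam_slots, cbind(sg$src_chrom, sg$src_index),
                         cbind(sg$dst_chrom, sg$dst_index))
      seg_truth <- rbind(seg_truth, data.frame(
        event = paste0("segmental", si),
        focal = gene_key(sg$src_chrom, sg$src_index),
        paralog = gene_key(sg$dst_chrom, sg$dst_index),
        n_anchors = sg$n_anchors, target_ks = sg$target_ks,
        stringsAsFactors = FALSE))
    }

    # random extra family genes, kept > 11 ordinals away from other family
    # genes so no unplanned tandem clusters can arise
    n_family_target <- round(layout$family_fraction * ng)
    extras_needed <- max(0, n_family_target -
                           (if (is.null(fam_slots)) 0 else nrow(fam_slots)))
    free <- which(role == "bg", arr.ind = TRUE)
    free <- free[sample.int(nrow(free)), , drop = FALSE]
    placed <- 0L
    for (r in seq_len(nrow(free))) {
      if (placed >= extras_needed) break
      ch <- free[r, 1]; i <- free[r, 2]
      near <- which(role[ch, ] != "bg")
      near <- near[abs(near - i) <= 25]
      if (length(near)) next
      role[ch, i] <- "family"
      placed <- placed + 1L
    }

    # base sequences per slot
    cds <- character(ng); prot <- character(ng)
    dim(cds) <- dim(prot) <- c(nch, gpc)
    for (ch in seq_len(nch)) for (i in seq_len(gpc)) {
      if (grepl("^tandem|^segsrc|^segdst", role[ch, i]) &&
          role[ch, i] != "bg") next  # filled below
      if (role[ch, i] == "family") {
        p <- random_wrky_protein("II")
        cds[ch, i] <- reverse_translate(p)
        prot[ch, i] <- p
      } else {
        p <- random_background_protein(sample(60:100, 1))
        cds[ch, i] <- reverse_translate(p)
        prot[ch, i] <- p
      }
    }
    # tandem arrays: members are light mutants of one family gene
    for (ti in seq_along(layout$tandem)) {
      td <- layout$tandem[[ti]]
      ords <- td$start + (0:(td$size - 1)) * (td$intervening + 1)
      base_p <- random_wrky_protein("II")
      base_c <- reverse_translate(base_p)
      sds <- sample.int(.Machine$integer.max - 1L, td$size)
      for (k in seq_along(ords)) {
        cc <- evolve_pair_to_ks(base_c, 0.1, seed = sds[k])
        cds[td$chrom, ords[k] + 1] <- cc
        prot[td$chrom, ords[k] + 1] <- translate_cds(cc)
      }
    }
    # segmental blocks: source genes random, destination = evolved copies
    for (si in seq_along(layout$segmental)) {
      sg <- layout$segmental[[si]]
      src <- sg$src_index + 0:sg$n_anchors
      dst <- sg$dst_index + 0:sg$n_anchors
      fam_p <- random_wrky_protein("II")
      cds[sg$src_chrom, sg$src_index + 1] <- reverse_translate(fam_p)
      prot[sg$src_chrom, sg$src_index + 1] <- fam_p
      for (k in seq_along(src)[-1]) {
        p <- random_background_protein(sample(80:120, 1))
        cds[sg$src_chrom, src[k] + 1] <- reverse_translate(p)
        prot[sg$src_chrom, src[k] + 1] <- p
      }
      sds <- sample.int(.Machine$integer.max - 1L, length(src))
      for (k in seq_along(src)) {
        cc <- evolve_pair_to_ks(cds[sg$src_chrom, src[k] + 1], sg$target_ks,
                                seed = sds[k])
        cds[sg$dst_chrom, dst[k] + 1] <- cc
        prot[sg$dst_chrom, dst[k] + 1] <- translate_cds(cc)
      }
    }

    # coordinates: sequential, non-overlapping, with 1-4 CDS segments
    rows <- list(); gff <- c("##gff-version 3")
    for (ch in seq_len(nch)) {
      pos <- 1L
      for (i in seq_len(gpc)) {
        id <- gene_key(ch, i - 1)
        clen <- nchar(cds[ch, i])
        nex <- sample(1:4, 1)
        # split CDS length into nex exon chunks (multiples of 3)
        ncod <- clen / 3
        cuts <- sort(sample(seq_len(ncod - 1), nex - 1))
        seg_cod <- diff(c(0, cuts, ncod))
        introns <- if (nex > 1) sample(80:200, nex - 1, replace = TRUE)
                   else integer(0)
        start <- pos + sample(6000L:12000L, 1)
        strand <- sample(c("+", "-"), 1)
        s <- start
        segs <- NULL
        for (e in seq_len(nex)) {
          en <- s + seg_cod[e] * 3 - 1
          segs <- rbind(segs, c(s, en))
          s <- en + 1 + if (e < nex) introns[e] else 0
        }
        end <- segs[nrow(segs), 2]
        chn <- paste0("chr", ch)
        gff <- c(gff,
          sprintf("%s\tfamevol\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  chn, start, end, strand, id),
          sprintf("%s\tfamevol\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                  chn, start, end, strand, id, id),
          sprintf("%s\tfamevol\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                  chn, segs[, 1], segs[, 2], strand, id, id))
        rows[[length(rows) + 1]] <- data.frame(
          id = id, chrom = chn, ordinal = i - 1L, start = start, end = end,
          strand = strand, n_exons = nex, cds_len = clen, role = role[ch, i],
          stringsAsFactors = FALSE)
        pos <- end
      }
    }
    genes <- do.call(rbind, rows)
    family_ids <- unique(c(genes$id[genes$role == "family"],
                           if (!is.null(tandem_truth)) tandem_truth$id,
                           if (!is.null(seg_truth)) seg_truth$focal,
                           if (!is.null(seg_truth)) seg_truth$paralog))
    cdsv <- setNames(cds[cbind(match(genes$chrom, paste0("chr", seq_len(nch))),
                               genes$ordinal + 1)], genes$id)
    protv <- setNames(prot[cbind(match(genes$chrom,
                                       paste0("chr", seq_len(nch))),
                                 genes$ordinal + 1)], genes$id)
    if (is.null(tandem_truth))
      tandem_truth <- data.frame(event = character(0), chrom = character(0),
                                 id = character(0), intervening = integer(0))
    if (is.null(seg_truth))
      seg_truth <- data.frame(event = character(0), focal = character(0),
                              paralog = character(0), n_anchors = integer(0),
                              target_ks = numeric(0))
    list(genes = genes, cds = cdsv, proteins = protv,
         family_ids = family_ids, gff = gff,
         truth = list(tandem = tandem_truth, segmental = seg_truth))
  })
}

#' Write a simulated genome to disk
#'
#' Emits `genome.gff3`, `cds.fasta`, `proteins.fasta`, `family.tsv` and the
#' truth tables (`truth_tandem.tsv`, `truth_segmental.tsv`) with a stable
#' column order.
#'
#' @param sim result of [sim_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sim$gff, file.path(dir, "genome.gff3"))
  write_fasta(sim$cds, file.path(dir, "cds.fasta"), "dna")
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"), "protein")
  writeLines(sim$family_ids, file.path(dir, "family.tsv"))
  write.table(sim$truth$tandem, file.path(dir, "truth_tandem.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$segmental, file.path(dir, "truth_segmental.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
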