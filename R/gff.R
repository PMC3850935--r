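# GFF3 parsing into gene models and gene-structure summaries.

#' Parse a GFF3 file into gene models
#'
#' Reads gene/mRNA/CDS features (via rtracklayer), resolves one
#' representative transcript per gene (the longest summed CDS), and computes
#' per-chromosome ordinal indices by start coordinate.  Coordinates stay
#' 1-based inclusive, as in the file.
#'
#' @param path GFF3 file path.
#' @return data.frame: `id`, `chrom`, `ordinal` (0-based, per chromosome by
#'   start), `start`, `end`, `strand`, `n_exons` (CDS segment count of the
#'   representative transcript), `cds_len` (bp).
#' @export
parse_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9))
    stop("malformed GFF3: expected 9 tab-separated fields at line ",
         body[which(nf != 9)[1]])
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  genes <- df[df$type == "gene", ]
  if (!nrow(genes)) {
    return(data.frame(id = character(0), chrom = character(0),
                      ordinal = integer(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_exons = integer(0), cds_len = integer(0)))
  }
  mrna <- df[df$type == "mRNA", ]
  cds <- df[df$type == "CDS", ]
  parent_of <- function(x) vapply(x$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  mrna$gene <- parent_of(mrna)
  cds$tx <- parent_of(cds)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tx <- mrna[mrna$gene == gid, ]
    if (nrow(tx)) {
      lens <- vapply(tx$ID, function(t)
        sum(cds$width[cds$tx == t]), 0)
      rep_tx <- tx$ID[which.max(lens)]
      seg <- cds[cds$tx == rep_tx, ]
    } else {
      seg <- cds[cds$tx == gid, ]
    }
    data.frame(id = gid, chrom = genes$seqnames[i],
               start = genes$start[i], end = genes$end[i],
               strand = as.character(genes$strand[i]),
               n_exons = nrow(seg), cds_len = sum(seg$width),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  out$ordinal <- as.integer(ave(out$start, out$chrom, FUN = function(s)
    rank(s, ties.method = "first") - 1L))
  rownames(out) <- NULL
  out[, c("id", "chrom", "ordinal", "start", "end", "strand", "n_exons",
          "cds_len")]
}

#' Per-gene exon count and CDS length
#'
#' @param genes gene table from [parse_gff3()].
#' @return data.frame `id`, `n_exons`, `cds_len`.
#' @export
summarize_gene_structure <- function(genes) {
  validate_genes(genes)
  if (!all(c("n_exons", "cds_len") %in% names(genes)))
    stop("gene table lacks CDS structure columns")
  genes[, c("id", "n_exons", "cds_len")]
}
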