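# Duplication-origin classification: tandem arrays from gene order,
# segmental blocks from flanking-gene anchors, dispersed otherwise.

validate_genes <- function(genes) {
  need <- c("id", "chrom", "ordinal", "start", "end")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (any(genes$start > genes$end)) stop("gene with start > end")
  invisible(genes)
}

#' Find tandemly duplicated family clusters
#'
#' Family genes on the same chromosome separated by at most `max_intervening`
#' intervening genes are clustered together; clusters are maximal and
#' singletons are dropped.
#'
#' @param genes gene table (`id`, `chrom`, `ordinal`, `start`, `end`, ...),
#'   e.g. from [parse_gff3()].
#' @param family_ids ids of the family members.
#' @param max_intervening maximum number of genes between consecutive
#'   cluster members (default 10).
#' @return data.frame with one row per cluster member: `cluster`, `chrom`,
#'   `id`, plus `max_gap` (largest intervening count seen in the cluster).
#' @export
find_tandem <- function(genes, family_ids, max_intervening = 10) {
  validate_genes(genes)
  missing <- setdiff(family_ids, genes$id)
  if (length(missing))
    stop("family ids absent from gene table: ",
         paste(missing, collapse = ", "))
  fam <- genes[genes$id %in% family_ids, ]
  out <- NULL
  cl_id <- 0L
  for (ch in unique(fam$chrom)) {
    f <- fam[fam$chrom == ch, ]
    f <- f[order(f$ordinal), ]
    if (nrow(f) < 2) next
    gaps <- diff(f$ordinal) - 1L
    grp <- cumsum(c(0L, as.integer(gaps > max_intervening)))
    for (g in unique(grp)) {
      members <- f$id[grp == g]
      if (length(members) < 2) next
      cl_id <- cl_id + 1L
      mg <- max(gaps[which(grp[-1] == g & grp[-length(grp)] == g)])
      out <- rbind(out, data.frame(cluster = cl_id, chrom = ch,
                                   id = members, max_gap = mg,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(cluster = integer(0), chrom = character(0),
                      id = character(0), max_gap = integer(0))
  out
}

#' Best non-self protein match for every gene
#'
#' All-against-all Smith-Waterman (BLOSUM62, affine gaps) under the same
#' scoring scheme as [prescreen_similarity()]; genes whose best bit score
#' falls below the cutoff map to `NA`.
#'
#' @param proteins named character vector of protein sequences (>= 2).
#' @param cutoff_bits minimum bit score to report a match.
#' @return named character vector: for each gene, the id of its best
#'   non-self match (or `NA`).
#' @export
best_nonself_matches <- function(proteins, cutoff_bits = 50) {
  n <- length(proteins)
  if (n < 2) stop("need >= 2 proteins")
  ids <- names(proteins)
  best <- setNames(rep(NA_character_, n), ids)
  S <- matrix(-Inf, n, n)
  for (i in seq_len(n - 1)) {
    sc <- sw_scores(proteins[[i]], proteins[(i + 1):n])
    S[i, (i + 1):n] <- sc
    S[(i + 1):n, i] <- sc
  }
  for (i in seq_len(n)) {
    j <- which.max(S[i, ])
    if (sw_bits(S[i, j]) >= cutoff_bits) best[i] <- ids[j]
  }
  best
}

gene_mid <- function(genes) (genes$start + genes$end) / 2

# Genes within `window_kb` of a focal gene's midpoint on its own chromosome
# (the focal gene itself excluded).
window_genes <- function(genes, focal_id, window_kb) {
  g <- genes[genes$id == focal_id, ]
  if (nrow(g) != 1) stop("gene not located: ", focal_id)
  same <- genes[genes$chrom == g$chrom & genes$id != focal_id, ]
  mid <- gene_mid(same)
  same[abs(mid - gene_mid(g)) <= window_kb * 1000, ]
}

#' Test a candidate segmental (block) duplication between two family genes
#'
#' Tallies flanking protein-coding genes within `window_kb` of the focal
#' gene whose best non-self match lies within `window_kb` of the candidate
#' paralog.  A pair with at least `min_anchors` such anchors is reported.
#'
#' @param focal_id,paralog_id the two family gene ids.
#' @param genes gene table (see [find_tandem()]).
#' @param best_match named vector from [best_nonself_matches()].
#' @param window_kb window half-width in kb around each gene midpoint
#'   (default 100).
#' @param min_anchors minimum anchor count (default 3).
#' @param reciprocal require the anchor match to be mutual (off by default:
#'   anchors are defined by a directional best non-self match).
#' @return `NULL`, or a list with `focal`, `paralog`, `anchors` (data.frame
#'   `gene`, `match`), `n_anchors`, `window_kb`.
#' @export
find_segmental <- function(focal_id, paralog_id, genes, best_match,
                           window_kb = 100, min_anchors = 3,
                           reciprocal = FALSE) {
  stopifnot(window_kb > 0)
  validate_genes(genes)
  flank <- window_genes(genes, focal_id, window_kb)
  flank <- flank[flank$id != paralog_id, ]
  target <- window_genes(genes, paralog_id, window_kb)
  target <- target[target$id != focal_id, ]
  if (!nrow(flank) || !nrow(target)) return(NULL)
  bm <- best_match[flank$id]
  ok <- !is.na(bm) & bm %in% target$id
  if (reciprocal) ok <- ok & !is.na(best_match[bm]) &
      best_match[bm] == flank$id
  anchors <- data.frame(gene = flank$id[ok], match = unname(bm[ok]),
                        stringsAsFactors = FALSE)
  if (nrow(anchors) < min_anchors) return(NULL)
  list(focal = focal_id, paralog = paralog_id, anchors = anchors,
       n_anchors = nrow(anchors), window_kb = window_kb)
}

#' Scan all family gene pairs for segmental blocks
#'
#' Convenience wrapper applying [find_segmental()] to every unordered pair
#' of family genes.
#'
#' @inheritParams find_segmental
#' @param family_ids family member ids.
#' @return list of block pairs (possibly empty).
#' @export
find_segmental_all <- function(family_ids, genes, best_match,
                               window_kb = 100, min_anchors = 3,
                               reciprocal = FALSE) {
  blocks <- list()
  fam <- family_ids
  if (length(fam) < 2) return(blocks)
  for (i in seq_len(length(fam) - 1)) for (j in (i + 1):length(fam)) {
    b <- find_segmental(fam[i], fam[j], genes, best_match, window_kb,
                        min_anchors, reciprocal)
    if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
  }
  blocks
}

#' Classify the duplication origin of each family gene
#'
#' A gene is `tandem` if it belongs to a tandem cluster, `segmental` if it
#' participates in an anchor-supported block pair, `both` if both flags are
#' set, and `dispersed` otherwise.
#'
#' @param family_ids family member ids.
#' @param tandem data.frame from [find_tandem()].
#' @param blocks list from [find_segmental_all()].
#' @return data.frame `gene`, `tandem`, `segmental`, `origin`.
#' @export
classify_origin <- function(family_ids, tandem, blocks) {
  in_tandem <- family_ids %in% tandem$id
  seg_ids <- unique(unlist(lapply(blocks, function(b) c(b$focal, b$paralog))))
  in_seg <- family_ids %in% seg_ids
  origin <- ifelse(in_tandem & in_seg, "both",
            ifelse(in_tandem, "tandem",
            ifelse(in_seg, "segmental", "dispersed")))
  data.frame(gene = family_ids, tandem = in_tandem, segmental = in_seg,
             origin = origin, stringsAsFactors = FALSE)
}

#' Summarize duplication origins with family-level percentages
#'
#' @param origin data.frame from [classify_origin()].
#' @return list with `n`, `counts` and `percent` (rounded to one decimal:
#'   `round(100 * count / n, 1)`), where `tandem`/`segmental` count every
#'   gene carrying that flag (genes flagged both appear in both counts).
#' @export
origin_summary <- function(origin) {
  n <- nrow(origin)
  counts <- c(segmental = sum(origin$segmental),
              tandem = sum(origin$tandem),
              both = sum(origin$tandem & origin$segmental),
              dispersed = sum(origin$origin == "dispersed"))
  list(n = n, counts = counts,
       percent = if (n > 0) round(100 * counts / n, 1)
                 else setNames(rep(NA_real_, length(counts)),
                               names(counts)))
}
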