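# WRKY domain detection and group I / II(a-e) / III classification.
#
# The family signature is the WRKYGQK heptapeptide followed, within a bounded
# gap, by a zinc finger: C2H2 (C-X4-5-C-X22-23-H-X-H) in groups I and II, or
# C2HC (C-X7-C-X23-H-X-C) in group III.

#' Domain pattern configuration
#'
#' @param heptapeptide literal heptapeptide variants to accept (exact match;
#'   the canonical signature is `WRKYGQK`).  Variants such as `WRKYGKK`
#'   can be added but are off by default.
#' @param c2h2_x1,c2h2_x2 allowed spacer lengths of the C2H2 finger
#'   (C-X{x1}-C-X{x2}-H-X-H).
#' @param c2hc_x1,c2hc_x2 allowed spacer lengths of the C2HC finger
#'   (C-X{x1}-C-X{x2}-H-X-C).
#' @param max_gap maximum residues between the heptapeptide end and the
#'   finger start.
#' @return list used by [scan_wrky_domains()].
#' @export
domain_pattern <- function(heptapeptide = "WRKYGQK",
                           c2h2_x1 = 4:5, c2h2_x2 = 22:23,
                           c2hc_x1 = 7, c2hc_x2 = 23,
                           max_gap = 50) {
  stopifnot(all(nchar(heptapeptide) == 7), length(c2h2_x1) > 0,
            length(c2h2_x2) > 0, max_gap >= 0)
  list(heptapeptide = heptapeptide,
       c2h2 = list(x1 = c2h2_x1, x2 = c2h2_x2, tail = "H.H"),
       c2hc = list(x1 = c2hc_x1, x2 = c2hc_x2, tail = "H.C"),
       max_gap = max_gap)
}

# All (overlapping) start positions of a perl regex in a string, 1-based.
regex_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Candidate zinc fingers of one type; overlapping spacings at the same start
# are resolved left-most-first (smallest x1, then x2).
finger_candidates <- function(seq, spec, type) {
  out <- NULL
  for (x1 in sort(spec$x1)) for (x2 in sort(spec$x2)) {
    pat <- sprintf("C.{%d}C.{%d}%s", x1, x2, spec$tail)
    len <- 1 + x1 + 1 + x2 + 3
    st <- regex_starts(seq, pat)
    if (length(st))
      out <- rbind(out, data.frame(start = st, end = st + len - 1,
                                   x1 = x1, x2 = x2, type = type))
  }
  if (is.null(out)) return(out)
  out <- out[order(out$start, out$x1, out$x2), , drop = FALSE]
  out[!duplicated(out$start), , drop = FALSE]
}

#' Scan a protein for WRKY domains
#'
#' Finds heptapeptide occurrences and pairs each (left to right) with the
#' nearest unused downstream zinc finger within the configured gap.
#' Positions in the result are 0-based.
#'
#' @param protein amino-acid sequence (single string; `X` tolerated).
#' @param pattern a [domain_pattern()] configuration.
#' @param id protein identifier stored in the result.
#' @return data.frame of hits: `protein`, `hepta_start`, `finger_type`,
#'   `finger_start`, `finger_end`, `span` (heptapeptide start to finger end),
#'   sorted by position.  Zero rows when nothing matches.
#' @export
scan_wrky_domains <- function(protein, pattern = domain_pattern(),
                              id = "query") {
  protein <- toupper(protein)
  hep <- sort(unique(unlist(lapply(pattern$heptapeptide, function(h)
    regex_starts(protein, h)))))
  empty <- data.frame(protein = character(0), hepta_start = integer(0),
                      finger_type = character(0), finger_start = integer(0),
                      finger_end = integer(0), span = integer(0))
  if (!length(hep)) return(empty)
  fins <- rbind(finger_candidates(protein, pattern$c2h2, "C2H2"),
                finger_candidates(protein, pattern$c2hc, "C2HC"))
  if (is.null(fins) || !nrow(fins)) return(empty)
  fins <- fins[order(fins$start, match(fins$type, c("C2H2", "C2HC"))), ]
  fins <- fins[!duplicated(fins$start), ]   # left-most-first per start
  used <- rep(FALSE, nrow(fins))
  hits <- NULL
  for (h in hep) {
    cand <- which(!used & fins$start > h &
                    fins$start - (h + 7) <= pattern$max_gap &
                    fins$start >= h + 7)
    if (!length(cand)) next
    k <- cand[which.min(fins$start[cand])]
    used[k] <- TRUE
    hits <- rbind(hits, data.frame(
      protein = id, hepta_start = h - 1L,
      finger_type = fins$type[k], finger_start = fins$start[k] - 1L,
      finger_end = fins$end[k] - 1L,
      span = fins$end[k] - h + 1L))
  }
  if (is.null(hits)) return(empty)
  hits[order(hits$hepta_start), , drop = FALSE]
}

#' Assign a protein to WRKY group I, II or III from its domain hits
#'
#' Two C2H2 domains give group I (domains labelled N and C); one C2H2 gives
#' group II; one C2HC gives group III; no hits is unassigned.  Proteins with
#' two or more hits of mixed finger type are assigned group I (domain count
#' dominates) and flagged.
#'
#' @param hits data.frame from [scan_wrky_domains()] for one protein.
#' @return list with `protein`, `n_domains`, `group` (`"I"`, `"II"`,
#'   `"III"`, `"unassigned"`), `subgroup` (`"none"`; see
#'   [assign_subgroup()]), `domain_labels` (N/C for group I) and `flagged`.
#' @export
classify_group <- function(hits) {
  n <- nrow(hits)
  id <- if (n) hits$protein[1] else NA_character_
  if (n == 0)
    return(list(protein = id, n_domains = 0L, group = "unassigned",
                subgroup = "none", domain_labels = character(0),
                flagged = FALSE))
  if (n >= 2) {
    flag <- any(hits$finger_type != "C2H2") || n > 2
    labels <- rep("", n)
    labels[1] <- "N"
    labels[n] <- "C"
    return(list(protein = id, n_domains = as.integer(n), group = "I",
                subgroup = "none", domain_labels = labels, flagged = flag))
  }
  group <- if (hits$finger_type[1] == "C2HC") "III" else "II"
  list(protein = id, n_domains = 1L, group = group, subgroup = "none",
       domain_labels = "", flagged = FALSE)
}

# BLAST-style bit score for a gapped BLOSUM62(11,1) local alignment.
sw_bits <- function(raw_score, lambda = 0.267, K = 0.041) {
  (lambda * raw_score - log(K)) / log(2)
}

# Smith-Waterman raw score(s) of `query` against subjects.
sw_scores <- function(query, subjects) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query, length(subjects))),
    Biostrings::AAStringSet(subjects),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

#' Local-alignment similarity prescreen against reference domains
#'
#' Smith-Waterman with BLOSUM62 and affine gaps (open 11, extend 1); the
#' best raw score against any reference is converted to bits with the
#' standard gapped Karlin-Altschul parameters (lambda 0.267, K 0.041) and
#' compared with `cutoff_bits`.
#'
#' @param query protein sequence.
#' @param refs character vector of reference domain/protein sequences.
#' @param cutoff_bits bit-score threshold (default 50, which admits every
#'   shipped reference domain while rejecting unrelated sequences).
#' @return list with `pass`, `bits`, `raw_score`, `best_ref` (index).
#' @export
prescreen_similarity <- function(query, refs, cutoff_bits = 50) {
  if (!length(refs)) stop("reference set must be non-empty")
  if (!nzchar(query)) stop("query must be non-empty")
  sc <- sw_scores(query, refs)
  best <- which.max(sc)
  bits <- sw_bits(sc[best])
  list(pass = bits >= cutoff_bits, bits = bits, raw_score = sc[best],
       best_ref = best)
}

#' Assign a group-II WRKY domain to subgroup IIa-IIe
#'
#' Nearest-labelled-reference classification: the domain is globally aligned
#' (BLOSUM62, affine gaps) against every labelled reference domain and takes
#' the subgroup of the closest under normalized distance (1 - fractional
#' identity).  Ties break to the alphabetically smallest subgroup label.
#'
#' @param domain_seq amino-acid sequence of the WRKY domain.
#' @param refs data.frame with columns `id`, `subgroup` (values
#'   `IIa`..`IIe`), `sequence`; all five subgroups must be represented.
#' @return list with `subgroup`, `distance`, `ref_id`.
#' @export
assign_subgroup <- function(domain_seq, refs = load_subgroup_refs()) {
  need <- paste0("II", letters[1:5])
  if (!all(need %in% refs$subgroup))
    stop("reference set must contain all five subgroups IIa-IIe; missing: ",
         paste(setdiff(need, refs$subgroup), collapse = ", "))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(domain_seq, nrow(refs))),
    Biostrings::AAStringSet(refs$sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  d <- 1 - Biostrings::pid(aln) / 100
  ord <- order(d, refs$subgroup)
  best <- ord[1]
  list(subgroup = refs$subgroup[best], distance = d[best],
       ref_id = refs$id[best])
}

#' Labelled reference WRKY domains for subgroup assignment
#'
#' Loads the synthetic labelled reference set shipped with the package
#' (three divergent domain sequences per subgroup IIa-IIe; constructed, not
#' taken from any real genome).
#'
#' @param path optional path to a TSV with columns `id`, `subgroup`,
#'   `sequence`.
#' @return data.frame of reference domains.
#' @export
load_subgroup_refs <- function(path = system.file(
    "extdata", "wrky_subgroup_refs_synthetic.tsv", package = "famevol")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from aligned domain sequences
#'
#' p-distance (proportion of differing, pairwise non-gap sites) followed by
#' [ape::nj()].
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (>= 3).
#' @return a `phylo` tree.
#' @export
build_nj_tree <- function(seqs) {
  if (length(seqs) < 3) stop("need >= 3 sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must be aligned to equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    D[i, j] <- D[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Classify a set of proteins into WRKY groups and subgroups
#'
#' Runs [scan_wrky_domains()] and [classify_group()] over a protein set and,
#' for group II proteins, [assign_subgroup()] on the domain sequence.
#'
#' @param proteins named character vector of protein sequences.
#' @param pattern a [domain_pattern()].
#' @param refs subgroup reference table (see [load_subgroup_refs()]); `NULL`
#'   skips subgroup assignment.
#' @return data.frame with one row per protein: `protein`, `n_domains`,
#'   `group`, `subgroup`, `flagged`.
#' @export
classify_family <- function(proteins, pattern = domain_pattern(),
                            refs = NULL) {
  rows <- lapply(names(proteins), function(nm) {
    hits <- scan_wrky_domains(proteins[[nm]], pattern, id = nm)
    cg <- classify_group(hits)
    cg$protein <- nm
    sub <- "none"
    if (cg$group == "II" && !is.null(refs)) {
      dom <- substr(proteins[[nm]], hits$hepta_start[1] + 1,
                    hits$finger_end[1] + 1)
      sub <- assign_subgroup(dom, refs)$subgroup
    }
    data.frame(protein = nm, n_domains = cg$n_domains, group = cg$group,
               subgroup = sub, flagged = cg$flagged,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(protein = character(0), n_domains = integer(0),
                      group = character(0), subgroup = character(0),
                      flagged = logical(0)))
  do.call(rbind, rows)
}
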