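# Promoter cis-element scanning against an IUPAC pattern catalog.

IUPAC_DNA <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
               D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Load a cis-element catalog
#'
#' Reads a TSV with columns `element` and `pattern` (IUPAC nucleotide
#' codes).  The shipped default catalog holds best-effort literal patterns
#' for the classical plant promoter elements (G-box, Box 4, ABRE,
#' TCA-element, MBS, HSE, TC-rich repeats, circadian, Skn-1, W-box); counts
#' are always relative to the catalog in use.
#'
#' @param path TSV path (default: the shipped catalog).
#' @return data.frame `element`, `pattern`.
#' @export
load_cis_catalog <- function(path = system.file("extdata",
                                                "cis_elements.tsv",
                                                package = "famevol")) {
  cat_ <- read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(cat_$element)) stop("duplicate element names in catalog")
  cat_
}

check_dna <- function(seqs) {
  for (nm in names(seqs)) {
    bad <- regexpr("[^ACGTRYSWKMBDHVN]", toupper(seqs[[nm]]))
    if (bad != -1)
      stop("non-DNA character in '", nm, "' at position ", bad)
  }
  invisible(TRUE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Overlapping occurrence count of one IUPAC pattern in one sequence.
# With strand = "both", distinct start positions matching the pattern in
# either orientation are counted (a palindromic pattern is not double
# counted).
count_pattern <- function(seq, pattern, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  subject <- Biostrings::DNAString(seq)
  fwd <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                             fixed = FALSE))
  if (strand == "forward") return(length(fwd))
  rc <- revcomp(pattern)
  rev <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(rc), subject,
                             fixed = FALSE))
  length(union(fwd, rev))
}

#' Count cis-element occurrences in promoter sequences
#'
#' Scans every promoter for every catalog element, counting overlapping
#' occurrences.  Both strands are scanned by default (promoter elements are
#' orientation-ambiguous); distinct start positions are counted so
#' palindromic elements are not double counted.
#'
#' @param promoters named character vector of promoter sequences (IUPAC
#'   DNA).
#' @param catalog data.frame `element`, `pattern` (see
#'   [load_cis_catalog()]).
#' @param strand `"both"` (default) or `"forward"`.
#' @param groups optional per-promoter group labels for per-group means.
#' @return list with `counts` (matrix promoters x elements) and
#'   `group_means` (matrix groups x elements, or `NULL`).
#' @export
scan_cis_elements <- function(promoters, catalog, strand = c("both",
                                                             "forward"),
                              groups = NULL) {
  strand <- match.arg(strand)
  if (is.null(names(promoters)))
    names(promoters) <- paste0("p", seq_along(promoters))
  check_dna(promoters)
  counts <- matrix(0L, length(promoters), nrow(catalog),
                   dimnames = list(names(promoters), catalog$element))
  for (j in seq_len(nrow(catalog)))
    counts[, j] <- vapply(promoters, count_pattern,
                          0L, pattern = catalog$pattern[j], strand = strand,
                          USE.NAMES = FALSE)
  gm <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(promoters))
    gm <- do.call(rbind, lapply(split(seq_along(groups), groups),
                                function(i) colMeans(counts[i, , drop = FALSE])))
  }
  list(counts = counts, group_means = gm)
}

#' Simulate promoter sequences with planted cis-elements
#'
#' Generates fixed-length promoters from a background nucleotide
#' distribution and plants the requested element copies verbatim at
#' non-overlapping random offsets.
#'
#' @param n number of promoters.
#' @param length promoter length in bp (default 1500, the span upstream of
#'   the translation start usually taken as the promoter).
#' @param elements list of `list(pattern =, copies =)` entries planted in
#'   every promoter.
#' @param background named probability vector over A/C/G/T for the
#'   background (restricting the support, e.g. `c(A = .5, T = .5)`, yields a
#'   background that cannot spell patterns using other letters).
#' @param seed integer seed.
#' @return list with `promoters` (named character vector) and `truth`
#'   (data.frame `promoter`, `pattern`, `offset` of planted copies,
#'   1-based).
#' @export
sim_promoters <- function(n, length = 1500, elements = list(),
                          background = c(A = .25, C = .25, G = .25, T = .25),
                          seed = 1) {
  planted_len <- sum(vapply(elements, function(e)
    nchar(e$pattern) * e$copies, 0))
  if (planted_len > length)
    stop("planted element content (", planted_len,
         " bp) exceeds promoter length (", length, " bp)")
  with_seed(seed, {
    proms <- character(n)
    truth <- NULL
    for (i in seq_len(n)) {
      s <- sample(names(background), length, replace = TRUE,
                  prob = background)
      taken <- rep(FALSE, length)
      for (el in elements) {
        L <- nchar(el$pattern)
        for (k in seq_len(el$copies)) {
          ok_starts <- which(vapply(seq_len(length - L + 1), function(st)
            !any(taken[st:(st + L - 1)]), TRUE))
          if (!length(ok_starts))
            stop("could not place planted element without overlap")
          st <- sample(ok_starts, 1)
          s[st:(st + L - 1)] <- strsplit(el$pattern, "")[[1]]
          taken[st:(st + L - 1)] <- TRUE
          truth <- rbind(truth, data.frame(
            promoter = paste0("p", i), pattern = el$pattern, offset = st,
            stringsAsFactors = FALSE))
        }
      }
      proms[i] <- paste(s, collapse = "")
    }
    names(proms) <- paste0("p", seq_len(n))
    if (is.null(truth))
      truth <- data.frame(promoter = character(0), pattern = character(0),
                          offset = integer(0))
    list(promoters = proms, truth = truth)
  })
}
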