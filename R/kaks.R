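# Nei-Gojobori (1986) Ka/Ks estimation, protein-guided codon alignment,
# block-level Ks summarisation with saturation filtering, and molecular-clock
# dating of duplication events.

# Per-codon synonymous site counts: the fraction of the nine single-nucleotide
# changes that are synonymous.  Changes creating a stop codon are counted as
# nonsynonymous (documented convention).
ng86_site_counts <- function() {
  if (!is.null(.famevol$ng86_sites)) return(.famevol$ng86_sites)
  cs <- codon_states()
  syn <- numeric(61)
  p <- cs$pairs
  for (r in seq_len(nrow(p))) if (p[r, "syn"] == 1) {
    syn[p[r, "i"]] <- syn[p[r, "i"]] + 1
    syn[p[r, "j"]] <- syn[p[r, "j"]] + 1
  }
  out <- cbind(S = syn / 3, N = 3 - syn / 3)
  rownames(out) <- cs$codons
  .famevol$ng86_sites <- out
  out
}

# Pairwise codon difference counts (Sd, Nd) with equal-weight averaging over
# all substitution orderings; paths through stop codons are discarded (if all
# orderings are blocked, every ordering is kept and stop-creating steps count
# as nonsynonymous).
ng86_pair_counts <- function() {
  if (!is.null(.famevol$ng86_pairs)) return(.famevol$ng86_pairs)
  cs <- codon_states()
  n <- 61L
  cm <- do.call(rbind, strsplit(cs$codons, ""))
  aa_of <- function(cod) {
    a <- Biostrings::GENETIC_CODE[cod]
    ifelse(is.na(a), "*", a)
  }
  Sd <- matrix(0, n, n)
  Nd <- matrix(0, n, n)
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dif <- which(cm[i, ] != cm[j, ])
      k <- length(dif)
      if (k == 0) next
      pm <- perms[[as.character(k)]]
      steps <- matrix(NA_real_, nrow(pm), 2)   # syn, nonsyn per ordering
      valid <- logical(nrow(pm))
      for (o in seq_len(nrow(pm))) {
        cur <- cm[i, ]
        s <- 0; ns <- 0; ok <- TRUE
        for (pos in dif[pm[o, ]]) {
          nxt <- cur
          nxt[pos] <- cm[j, pos]
          a1 <- aa_of(paste(cur, collapse = ""))
          a2 <- aa_of(paste(nxt, collapse = ""))
          if (a2 == "*" || a1 == "*") ok <- FALSE
          if (a1 == a2 && a1 != "*") s <- s + 1 else ns <- ns + 1
          cur <- nxt
        }
        steps[o, ] <- c(s, ns)
        valid[o] <- ok
      }
      use <- if (any(valid)) valid else rep(TRUE, nrow(pm))
      Sd[i, j] <- Sd[j, i] <- mean(steps[use, 1])
      Nd[i, j] <- Nd[j, i] <- mean(steps[use, 2])
    }
  }
  .famevol$ng86_pairs <- list(Sd = Sd, Nd = Nd)
  .famevol$ng86_pairs
}

jc_correct <- function(p, what) {
  if (p >= 0.75)
    stop("saturation: proportion of ", what,
         " differences (", signif(p, 4), ") is >= 3/4, Jukes-Cantor ",
         "correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori Ka/Ks for a pair of aligned coding sequences
#'
#' Implements the NG86 method: per-codon synonymous/nonsynonymous site
#' counting averaged over the two sequences, equal-weight averaging over all
#' substitution pathways for codons differing at 2-3 positions, and
#' Jukes-Cantor correction of the raw proportions.  Codons containing gaps or
#' ambiguity characters in either row are excluded pairwise.
#'
#' @param x,y in-frame aligned CDS strings of equal length.
#' @return object of class `kaks_estimate`: list with `ka`, `ks`, `omega`,
#'   site counts `N`, `S`, difference counts `Nd`, `Sd`, and the number of
#'   compared codons.
#' @examples
#' # one synonymous third-position change among six glycine codons
#' ng86_ka_ks(strrep("GGT", 6), paste0(strrep("GGT", 5), "GGC"))
#' @export
ng86_ka_ks <- function(x, y) {
  cs <- codon_states()
  cx <- split_codons(toupper(x))
  cy <- split_codons(toupper(y))
  if (length(cx) != length(cy)) stop("sequences must have equal codon length")
  ix <- match(cx, cs$codons)
  iy <- match(cy, cs$codons)
  stopx <- is.na(ix) & !grepl("-|[^ACGT]", cx)
  stopy <- is.na(iy) & !grepl("-|[^ACGT]", cy)
  if (any(stopx | stopy))
    stop("internal stop codon at codon position ", which(stopx | stopy)[1])
  keep <- !is.na(ix) & !is.na(iy)
  if (!any(keep)) stop("no comparable (gap-free, unambiguous) codons")
  ix <- ix[keep]; iy <- iy[keep]
  sites <- ng86_site_counts()
  S <- (sum(sites[ix, "S"]) + sum(sites[iy, "S"])) / 2
  N <- (sum(sites[ix, "N"]) + sum(sites[iy, "N"])) / 2
  pc <- ng86_pair_counts()
  Sd <- sum(pc$Sd[cbind(ix, iy)])
  Nd <- sum(pc$Nd[cbind(ix, iy)])
  ps <- Sd / S
  pn <- Nd / N
  ks <- jc_correct(ps, "synonymous")
  ka <- jc_correct(pn, "nonsynonymous")
  structure(list(ka = ka, ks = ks,
                 omega = if (ks > 0) ka / ks else NA_real_,
                 N = N, S = S, Nd = Nd, Sd = Sd, n_codons = sum(keep)),
            class = "kaks_estimate")
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("NG86 Ka/Ks over %d codons\n", x$n_codons))
  cat(sprintf("  Ka = %.4f (Nd = %.2f / N = %.1f)\n", x$ka, x$Nd, x$N))
  cat(sprintf("  Ks = %.4f (Sd = %.2f / S = %.1f)\n", x$ks, x$Sd, x$S))
  cat(sprintf("  omega (Ka/Ks) = %s\n",
              if (is.na(x$omega)) "undefined (Ks = 0)"
              else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each amino-acid column expands to one codon column; protein gaps become
#' triplet gaps.  Every CDS must translate exactly to its ungapped protein
#' row.
#'
#' @param prot_aln named character vector: aligned protein sequences.
#' @param cds named character vector: ungapped in-frame CDS, same names.
#' @return named character vector of gapped CDS (class `codon_alignment`).
#' @export
codon_align <- function(prot_aln, cds) {
  if (!all(names(prot_aln) %in% names(cds)))
    stop("missing CDS for: ",
         paste(setdiff(names(prot_aln), names(cds)), collapse = ", "))
  out <- vapply(names(prot_aln), function(nm) {
    aa <- strsplit(prot_aln[[nm]], "")[[1]]
    codons <- split_codons(toupper(cds[[nm]]))
    tr <- vapply(codons, function(cod) {
      a <- Biostrings::GENETIC_CODE[cod]
      if (is.na(a)) if (grepl("[^ACGT]", cod)) "X" else "*" else unname(a)
    }, "")
    if (any(tr == "*"))
      stop("codon back-translation error in '", nm, "': internal stop at ",
           "codon ", which(tr == "*")[1])
    ung <- aa[aa != "-"]
    if (length(ung) != length(codons))
      stop("codon back-translation error in '", nm, "': ", length(codons),
           " codons but ", length(ung), " aligned residues")
    mism <- which(!(ung == tr | ung == "X" | tr == "X"))
    if (length(mism))
      stop("codon back-translation error in '", nm, "': CDS does not ",
           "translate to the aligned protein (first mismatch at residue ",
           mism[1], ")")
    res <- character(length(aa))
    res[aa == "-"] <- "---"
    res[aa != "-"] <- codons
    paste(res, collapse = "")
  }, "")
  structure(out, class = c("codon_alignment", "character"))
}

#' Protein-guided Ka/Ks for a pair of unaligned CDS
#'
#' Translates both CDS, aligns the proteins globally (BLOSUM62, affine
#' gaps), back-translates the alignment with [codon_align()] and applies
#' [ng86_ka_ks()].
#'
#' @param cds_x,cds_y in-frame CDS strings (no internal stops; a trailing
#'   stop codon is trimmed).
#' @return a `kaks_estimate` (see [ng86_ka_ks()]).
#' @export
align_pair_kaks <- function(cds_x, cds_y) {
  trim <- function(s) {
    cod <- split_codons(toupper(s))
    last <- Biostrings::GENETIC_CODE[cod[length(cod)]]
    if (!is.na(last) && last == "*") cod <- cod[-length(cod)]
    paste(cod, collapse = "")
  }
  cds <- c(x = trim(cds_x), y = trim(cds_y))
  prot <- vapply(cds, translate_cds, "")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot[["x"]]), Biostrings::AAString(prot[["y"]]),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pa <- c(x = as.character(Biostrings::alignedPattern(al)),
          y = as.character(Biostrings::alignedSubject(al)))
  ca <- codon_align(pa, cds)
  ng86_ka_ks(ca[["x"]], ca[["y"]])
}

#' Summarize anchor Ks values for a duplicated block
#'
#' Anchors with Ks above the saturation cutoff are discarded, then the mean
#' and sample standard deviation are taken over the rest.
#'
#' @param ks numeric vector of per-anchor Ks values.
#' @param cutoff saturation cutoff; anchors with Ks > cutoff are dropped
#'   (default 1.0).
#' @return list with `mean_ks`, `sd_ks`, `n_retained`, `all_removed`.
#' @export
block_ks <- function(ks, cutoff = 1.0) {
  stopifnot(length(ks) >= 1, is.numeric(ks))
  keep <- ks <= cutoff
  if (!any(keep))
    return(list(mean_ks = NA_real_, sd_ks = NA_real_, n_retained = 0L,
                all_removed = TRUE))
  k <- ks[keep]
  list(mean_ks = mean(k),
       sd_ks = if (length(k) > 1) sd(k) else 0,
       n_retained = length(k), all_removed = FALSE)
}

# Round half away from zero, the convention used for table ages in Myr.
round_half_up <- function(x) floor(x + 0.5)

#' Date a duplication event from its mean Ks
#'
#' Applies the synonymous molecular clock T = Ks / (2 lambda), reported in
#' million years.
#'
#' @param mean_ks mean synonymous divergence of the block (>= 0).
#' @param lambda clock rate in synonymous substitutions/site/year (e.g.
#'   6.1e-9 for soybean, 1.5e-8 for Arabidopsis).
#' @param rounded if `TRUE`, round to the nearest integer Myr (half-up), the
#'   convention used in summary tables.
#' @return age in Myr.
#' @examples
#' date_duplication(0.60, lambda = 6.1e-9, rounded = TRUE)  # 49 Myr
#' date_duplication(0.17, lambda = 6.1e-9, rounded = TRUE)  # 14 Myr
#' @export
date_duplication <- function(mean_ks, lambda = 6.1e-9, rounded = FALSE) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(mean_ks < 0)) stop("mean Ks must be >= 0")
  t_myr <- mean_ks / (2 * lambda) / 1e6
  if (rounded) round_half_up(t_myr) else t_myr
}
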