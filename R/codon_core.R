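# Genetic-code machinery shared by the simulator, the NG86 estimator and the
# maximum-likelihood codon models.  All codon-indexed structures use the 61
# sense codons of the standard code, ordered alphabetically over A<C<G<T.

.NUC <- c("A", "C", "G", "T")

#' Codon state table for the standard genetic code
#'
#' Returns the internal table of the 61 sense codons: their order defines the
#' state indexing used by [codon_rate_matrix()] and the likelihood engine.
#'
#' @return A list with elements `codons` (character vector of 61 codons,
#'   alphabetical), `aa` (encoded amino acid per codon), `pairs` (integer
#'   matrix of single-nucleotide neighbour pairs with columns `i`, `j`,
#'   `ts` (1 = transition), `syn` (1 = synonymous), `pos` (changed codon
#'   position)), and `neighbors` (list mapping each codon index to its sense
#'   single-nucleotide neighbours).
#' @export
codon_states <- function() {
  if (!is.null(.famevol$codon_states)) return(.famevol$codon_states)
  all64 <- as.character(outer(outer(.NUC, .NUC, paste0), .NUC, paste0))
  all64 <- sort(all64)
  gc <- Biostrings::GENETIC_CODE[all64]
  sense <- all64[gc != "*"]
  aa <- unname(gc[gc != "*"])
  n <- length(sense)
  stopifnot(n == 61L)
  cmat <- do.call(rbind, strsplit(sense, ""))
  pr <- vector("list", 3L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (pos in 1:3) {
      for (nt in .NUC) {
        if (nt == cmat[i, pos]) next
        trip <- cmat[i, ]
        trip[pos] <- nt
        j <- match(paste(trip, collapse = ""), sense)
        if (is.na(j)) next            # change to a stop codon: no state
        if (j <= i) next              # keep each unordered pair once
        ts <- (cmat[i, pos] %in% c("A", "G") && nt %in% c("A", "G")) ||
              (cmat[i, pos] %in% c("C", "T") && nt %in% c("C", "T"))
        k <- k + 1L
        pr[[k]] <- c(i, j, as.integer(ts), as.integer(aa[i] == aa[j]), pos)
      }
    }
  }
  pairs <- do.call(rbind, pr[seq_len(k)])
  colnames(pairs) <- c("i", "j", "ts", "syn", "pos")
  neighbors <- split(c(pairs[, "j"], pairs[, "i"]),
                     c(pairs[, "i"], pairs[, "j"]))
  neighbors <- lapply(seq_len(n), function(i) {
    v <- neighbors[[as.character(i)]]
    if (is.null(v)) integer(0) else sort(unique(v))
  })
  out <- list(codons = sense, aa = aa, pairs = pairs, neighbors = neighbors)
  .famevol$codon_states <- out
  out
}

#' GY94 codon rate matrix
#'
#' Builds the 61x61 generator of the Goldman--Yang codon substitution process:
#' multi-nucleotide changes are forbidden, transitions are scaled by `kappa`,
#' nonsynonymous changes by `omega`, and the target-codon frequency enters
#' every rate.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi stationary codon frequencies over the 61 sense codons.
#' @param scale if `TRUE` (default) the generator is rescaled so the mean
#'   substitution rate at stationarity is 1 (branch lengths are then expected
#'   substitutions per codon).
#' @return A 61x61 matrix with zero row sums.
#' @export
codon_rate_matrix <- function(kappa, omega, pi = rep(1 / 61, 61),
                              scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61, all(pi >= 0))
  pi <- pi / sum(pi)
  cs <- codon_states()
  p <- cs$pairs
  Q <- matrix(0, 61, 61, dimnames = list(cs$codons, cs$codons))
  rate <- ifelse(p[, "ts"] == 1, kappa, 1) * ifelse(p[, "syn"] == 1, 1, omega)
  Q[p[, c("i", "j")]] <- rate * pi[p[, "j"]]
  Q[p[, c("j", "i")]] <- rate * pi[p[, "i"]]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# Mean substitution rate of the *unscaled* GY94 generator at stationarity.
codon_mean_rate <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  pi <- pi / sum(pi)
  cs <- codon_states()
  p <- cs$pairs
  rate <- ifelse(p[, "ts"] == 1, kappa, 1) * ifelse(p[, "syn"] == 1, 1, omega)
  # each unordered pair contributes pi_i q_ij + pi_j q_ji = 2 rate pi_i pi_j
  2 * sum(rate * pi[p[, "i"]] * pi[p[, "j"]])
}

# Spectral decomposition of the (reversible) GY94 generator, for fast
# computation of transition matrices at many branch lengths.
codon_eigen <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  pi <- pi / sum(pi)
  Q <- codon_rate_matrix(kappa, omega, pi, scale = FALSE)
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))       # D^{1/2} Q D^{-1/2}, symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sp,                      # D^{-1/2} V  (row scaling)
       Uinv = t(e$vectors * sp),                # V' D^{1/2}
       values = e$values)
}

# P(t) = exp(Qt) from a codon_eigen() decomposition.  Small negative entries
# from round-off are clamped at zero.
codon_probmat <- function(eg, t) {
  if (t == 0) return(diag(nrow(eg$U)))
  P <- (eg$U * rep(exp(eg$values * t), each = nrow(eg$U))) %*% eg$Uinv
  P[P < 0] <- 0
  P
}

#' F3x4 codon frequencies
#'
#' Estimates codon frequencies as the product of position-specific nucleotide
#' frequencies (the PAML F3x4 convention), renormalized over sense codons.
#'
#' @param seqs character vector of in-frame CDS sequences (gaps tolerated).
#' @return numeric vector of 61 frequencies summing to 1.
#' @export
f3x4_frequencies <- function(seqs) {
  cod <- unlist(lapply(seqs, split_codons))
  cod <- cod[!grepl("[^ACGT]", cod)]
  if (!length(cod)) stop("no unambiguous codons to estimate frequencies from")
  m <- do.call(rbind, strsplit(cod, ""))
  f <- lapply(1:3, function(p) {
    tab <- table(factor(m[, p], levels = .NUC))
    as.numeric(tab) / sum(tab)
  })
  cs <- codon_states()
  cm <- do.call(rbind, strsplit(cs$codons, ""))
  pi <- f[[1]][match(cm[, 1], .NUC)] *
        f[[2]][match(cm[, 2], .NUC)] *
        f[[3]][match(cm[, 3], .NUC)]
  pi / sum(pi)
}

# Split an in-frame sequence into codons.
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3: ", n)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

# Translate an in-frame ungapped CDS; stops become "*".
translate_cds <- function(x) {
  cod <- split_codons(toupper(x))
  aa <- Biostrings::GENETIC_CODE[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Integer codon-state matrix (taxa x sites) from named CDS strings.
# Gap codons ("---") and codons with ambiguity become NA (missing data);
# internal stop codons raise an error.
codon_index_matrix <- function(seqs) {
  cs <- codon_states()
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length")
  rows <- lapply(seqs, function(s) {
    cod <- split_codons(toupper(s))
    idx <- match(cod, cs$codons)
    bad <- is.na(idx) & !grepl("-|[^ACGT]", cod)
    if (any(bad))
      stop("internal stop codon at codon position ", which(bad)[1])
    idx
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  m
}
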