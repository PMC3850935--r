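# Expression-atlas normalization, clustering and breadth classification.

#' Row-wise Z-score standardization of an expression matrix
#'
#' Each row is transformed to (x - mean) / sd using the population standard
#' deviation; constant rows map to all zeros (documented convention).
#'
#' @param x numeric matrix, genes in rows, tissues in columns (>= 2).
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 tissues")
  if (any(x < 0)) stop("expression values must be non-negative")
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))
  z <- (x - mu) / ifelse(sdp == 0, 1, sdp)
  z[sdp == 0, ] <- 0
  z
}

#' Hierarchical clustering of expression profiles by Pearson correlation
#'
#' Average-linkage clustering under distance 1 - Pearson correlation.
#' Constant rows (zero variance, correlation undefined) are excluded with a
#' warning.  Leaf order is made deterministic by ordering tied merges by
#' original row index.
#'
#' @param z standardized matrix from [zscore_rows()] (raw values work too).
#' @return list with `hclust` (the dendrogram), `order` (leaf order as row
#'   names), `excluded` (names of constant rows).
#' @export
cluster_expression <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("need >= 2 genes")
  v <- apply(z, 1, var)
  excluded <- rownames(z)[v == 0]
  if (length(excluded))
    warning(length(excluded), " constant-profile gene(s) excluded: ",
            paste(excluded, collapse = ", "))
  zz <- z[v > 0, , drop = FALSE]
  if (nrow(zz) < 2) stop("fewer than 2 non-constant genes")
  d <- as.dist(1 - cor(t(zz)))
  hc <- hclust(d, method = "average")
  list(hclust = hc, order = rownames(zz)[hc$order], excluded = excluded)
}

#' Classify expression breadth per gene
#'
#' Categories: `not_detected` (all tissues below `expressed_cutoff`),
#' `constitutive` (all tissues at or above the cutoff),
#' `single_tissue_peak` (exactly one tissue passing the peak rule:
#' Z >= `peak_z` and the row maximum), otherwise `intermediate`.
#'
#' @param x raw expression matrix (genes x tissues).
#' @param expressed_cutoff expression floor in the matrix units (default 1).
#' @param peak_z Z-score threshold of the peak rule (default 1.5).
#' @return data.frame `gene`, `breadth`, `peak_tissue` (NA unless a single
#'   peak).
#' @export
classify_breadth <- function(x, expressed_cutoff = 1, peak_z = 1.5) {
  x <- as.matrix(x)
  z <- zscore_rows(x)
  breadth <- character(nrow(x))
  peak <- rep(NA_character_, nrow(x))
  for (i in seq_len(nrow(x))) {
    peaks <- which(z[i, ] >= peak_z & x[i, ] == max(x[i, ]))
    if (all(x[i, ] < expressed_cutoff)) {
      breadth[i] <- "not_detected"
    } else if (all(x[i, ] >= expressed_cutoff)) {
      breadth[i] <- "constitutive"
    } else if (length(peaks) == 1) {
      breadth[i] <- "single_tissue_peak"
      peak[i] <- colnames(x)[peaks]
    } else {
      breadth[i] <- "intermediate"
    }
  }
  data.frame(gene = rownames(x) %||% as.character(seq_len(nrow(x))),
             breadth = breadth, peak_tissue = peak,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a tissue expression atlas with group-structured peaks
#'
#' Background expression is log-normal; genes of a labelled group share a
#' planted peak tissue whose (log-scale) elevation is `effect_size` standard
#' deviations.  With `effect_size = 0` no tissue is preferentially elevated.
#'
#' @param groups character vector of per-gene group labels; genes labelled
#'   `"none"` get no planted peak.
#' @param tissues tissue names (>= 2).
#' @param effect_size peak elevation in units of the background log-sd.
#' @param base_sd log-scale background standard deviation (0 gives constant
#'   rows).
#' @param seed integer seed.
#' @return list with `x` (matrix genes x tissues) and `truth` (data.frame
#'   `gene`, `group`, `peak_tissue`).
#' @export
sim_expression <- function(groups, tissues, effect_size = 5, base_sd = 1,
                           seed = 1) {
  if (length(tissues) < 2) stop("need >= 2 tissues")
  ng <- length(groups)
  with_seed(seed, {
    gl <- setdiff(unique(groups), "none")
    peak_of <- setNames(sample(tissues, length(gl),
                               replace = length(gl) > length(tissues)), gl)
    x <- matrix(exp(rnorm(ng * length(tissues), 0, base_sd)), ng,
                dimnames = list(paste0("gene", seq_len(ng)), tissues))
    truth_peak <- rep(NA_character_, ng)
    for (i in seq_len(ng)) {
      if (groups[i] == "none") next
      pt <- peak_of[[groups[i]]]
      x[i, pt] <- x[i, pt] * exp(effect_size * base_sd)
      truth_peak[i] <- pt
    }
    list(x = x, truth = data.frame(gene = rownames(x), group = groups,
                                   peak_tissue = truth_peak,
                                   stringsAsFactors = FALSE))
  })
}
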