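# R-side driver for the codon likelihood kernel: tree preparation, site-class
# structures, and pattern compression.

# Validate a rooted/unrooted ape tree and return postorder edge structures.
prep_tree <- function(tree, foreground = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  fg <- rep(FALSE, nrow(tree$edge))
  if (!is.null(foreground)) {
    if (is.numeric(foreground)) {
      fg[as.integer(foreground)] <- TRUE
    } else {
      labs <- c(tree$tip.label,
                if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
                else tree$node.label)
      # "#1" suffixes (PAML convention) are accepted on either side
      want <- sub("\\s*#1$", "", foreground)
      child <- sub("\\s*#1$", "", labs[tree$edge[, 2]])
      fg[!is.na(child) & child %in% want] <- TRUE
    }
    if (!any(fg)) stop("no foreground branches matched")
  }
  list(tree = tree, edge = tree$edge, elen = tree$edge.length,
       nnode = ntip + tree$Nnode, root = root, ntip = ntip, fg = fg)
}

# Compress an integer codon matrix (taxa x sites) into unique site patterns.
site_patterns <- function(m) {
  key <- apply(m, 2, paste, collapse = ".")
  u <- !duplicated(key)
  tips <- m[, u, drop = FALSE]
  tips[is.na(tips)] <- 0L
  list(tips = tips, weight = as.vector(table(key)[key[u]]),
       map = match(key, key[u]))
}

# Site-class structure: weights plus background/foreground omega per class.
# Site models have om_fg == om_bg.
class_structure <- function(weights, om_bg, om_fg = om_bg) {
  stopifnot(length(weights) == length(om_bg), length(om_bg) == length(om_fg),
            abs(sum(weights) - 1) < 1e-9, all(om_bg >= 0), all(om_fg >= 0))
  list(weights = weights, om_bg = om_bg, om_fg = om_fg)
}

# Per-pattern, per-class likelihoods.  Returns list(lik = npat x K, pat).
site_class_liks <- function(pat, pt, kappa, cls, pi) {
  omegas <- sort(unique(c(cls$om_bg, cls$om_fg)))
  K <- length(cls$weights)
  nedge <- nrow(pt$edge)
  oidx <- matrix(0L, K, nedge)
  for (k in seq_len(K)) {
    ob <- match(cls$om_bg[k], omegas)
    of <- match(cls$om_fg[k], omegas)
    oidx[k, ] <- ifelse(pt$fg, of, ob)
  }
  normfactor <- sum(vapply(seq_len(K), function(k)
    cls$weights[k] * codon_mean_rate(kappa, cls$om_bg[k], pi), 0))
  cs <- codon_states()
  lik <- codon_site_lik_cpp(pat$tips, pt$edge, pt$elen, pt$nnode, pt$root,
                            pi, kappa, omegas, oidx, normfactor,
                            cs$pairs[, 1:4, drop = FALSE])
  lik
}

#' Log-likelihood of a codon alignment under a GY94 site/branch-site model
#'
#' Computes the phylogenetic log-likelihood by Felsenstein pruning over the 61
#' sense-codon states.  Site-class models mix per-site likelihoods over
#' classes with their proportions; branch-site structures apply class-specific
#' omega on foreground versus background branches.
#'
#' @param aln named character vector of aligned in-frame CDS (or a list as
#'   returned by [sim_codon_alignment()]).
#' @param tree rooted `phylo` with branch lengths; tip labels must match
#'   alignment names.
#' @param kappa transition/transversion ratio.
#' @param weights site-class proportions (sum to 1).
#' @param omega_bg per-class omega on background branches.
#' @param omega_fg per-class omega on foreground branches (defaults to
#'   `omega_bg`; site models need not set it).
#' @param pi codon frequencies (default uniform over the 61 sense codons).
#' @param foreground labels of nodes/tips whose parent edges are foreground,
#'   or numeric edge indices; `NULL` for site models.
#' @return the log-likelihood (numeric scalar).
#' @export
codon_loglik <- function(aln, tree, kappa, weights = 1, omega_bg,
                         omega_fg = omega_bg, pi = rep(1 / 61, 61),
                         foreground = NULL) {
  if (is.list(aln) && !is.null(aln$alignment)) aln <- aln$alignment
  pt <- prep_tree(tree, foreground)
  if (!all(pt$tree$tip.label %in% names(aln)))
    stop("alignment is missing sequences for tips: ",
         paste(setdiff(pt$tree$tip.label, names(aln)), collapse = ", "))
  m <- codon_index_matrix(aln[pt$tree$tip.label])
  pat <- site_patterns(m)
  cls <- class_structure(weights, omega_bg, omega_fg)
  lik <- site_class_liks(pat, pt, kappa, cls, pi)
  mix <- as.vector(lik %*% cls$weights)
  if (any(mix <= 0)) return(-Inf)
  sum(pat$weight * log(mix))
}
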