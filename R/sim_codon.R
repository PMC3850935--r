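# Codon alignment simulation under GY94-style site and branch-site regimes.
# The simulator uses the same rate structure and normalization as the ML
# engine, so parameter recovery is a fair test.

#' Omega regimes for codon simulation
#'
#' Constructors for the three supported selection regimes: a single ratio
#' (`M0`), a discrete mixture of site classes, and the branch-site layout
#' with four site classes (0, 1, 2a, 2b) and foreground-specific omega.
#'
#' For the branch-site regime the class proportions follow the standard
#' parametrisation: `p2a = (1-p0-p1) p0/(p0+p1)` and
#' `p2b = (1-p0-p1) p1/(p0+p1)` unless given explicitly.
#'
#' @param omega,omega0,omega2 omega values (>= 0); `omega2` applies on
#'   foreground branches in classes 2a/2b.
#' @param p,p0,p1,p2a,p2b class proportions.
#' @param foreground labels of nodes/tips whose parent edges are foreground.
#' @return a regime object consumed by [sim_codon_alignment()] and
#'   [fit_codon_model()].
#' @export
regime_m0 <- function(omega) {
  stopifnot(omega >= 0)
  structure(list(type = "M0", omega = omega), class = "omega_regime")
}

#' @rdname regime_m0
#' @export
regime_discrete <- function(p, omega) {
  stopifnot(length(p) == length(omega), all(omega >= 0), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) stop("class proportions must sum to 1")
  structure(list(type = "discrete", p = p, omega = omega),
            class = "omega_regime")
}

#' @rdname regime_m0
#' @export
regime_branch_site <- function(p0, p1, omega0, omega2, foreground,
                               p2a = NULL, p2b = NULL) {
  if (missing(foreground) || length(foreground) == 0)
    stop("branch-site regime requires a non-empty foreground branch set")
  stopifnot(omega0 >= 0, omega2 >= 0, p0 >= 0, p1 >= 0)
  if (is.null(p2a)) {
    q <- 1 - p0 - p1
    if (p0 + p1 <= 0) stop("p0 + p1 must be > 0 to derive p2a/p2b")
    p2a <- q * p0 / (p0 + p1)
    p2b <- q * p1 / (p0 + p1)
  }
  p <- c(p0, p1, p2a, p2b)
  if (abs(sum(p) - 1) > 1e-9) stop("class proportions must sum to 1")
  structure(list(type = "branch_site", p = p, omega0 = omega0,
                 omega2 = omega2, foreground = foreground),
            class = "omega_regime")
}

# Translate a regime into the internal class structure.
regime_classes <- function(regime) {
  switch(regime$type,
    M0 = class_structure(1, regime$omega),
    discrete = class_structure(regime$p, regime$omega),
    branch_site = class_structure(
      regime$p,
      om_bg = c(regime$omega0, 1, regime$omega0, 1),
      om_fg = c(regime$omega0, 1, regime$omega2, regime$omega2)),
    stop("unknown regime type"))
}

#' Simulate a codon alignment on a tree
#'
#' Evolves in-frame CDS down `tree` under a continuous-time GY94 codon model
#' (single-nucleotide neighbour moves, `kappa` on transitions, class-specific
#' omega on nonsynonymous changes; matrix exponentiation per branch).  The
#' generator is normalized exactly as in [codon_loglik()], so branch lengths
#' are expected substitutions per codon under the background regime.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param n_codons number of codons (>= 1).
#' @param regime an omega regime from [regime_m0()], [regime_discrete()] or
#'   [regime_branch_site()].
#' @param kappa transition/transversion ratio.
#' @param pi codon frequencies (default uniform over 61 sense codons).
#' @param seed integer seed.
#' @return list with `alignment` (named CDS strings, one per tip; no stop
#'   codons), `site_class` (true per-site class labels), `tree`, `regime`,
#'   `kappa`.
#' @export
sim_codon_alignment <- function(tree, n_codons, regime, kappa = 2,
                                pi = rep(1 / 61, 61), seed = 1) {
  stopifnot(n_codons >= 1)
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 leaves")
  cls <- regime_classes(regime)
  fg <- if (regime$type == "branch_site") regime$foreground else NULL
  pt <- prep_tree(tree, fg)
  pi <- pi / sum(pi)
  cs <- codon_states()
  K <- length(cls$weights)
  normfactor <- sum(vapply(seq_len(K), function(k)
    cls$weights[k] * codon_mean_rate(kappa, cls$om_bg[k], pi), 0))
  with_seed(seed, {
    site_class <- sample.int(K, n_codons, replace = TRUE,
                             prob = cls$weights)
    omegas <- sort(unique(c(cls$om_bg, cls$om_fg)))
    egs <- lapply(omegas, function(w) codon_eigen(kappa, w, pi))
    states <- matrix(NA_integer_, pt$nnode, n_codons)
    states[pt$root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
    # preorder = reversed postorder edge list
    for (e in rev(seq_len(nrow(pt$edge)))) {
      par <- pt$edge[e, 1]; chd <- pt$edge[e, 2]
      t_e <- pt$elen[e] / normfactor
      for (k in seq_len(K)) {
        w <- if (pt$fg[e]) cls$om_fg[k] else cls$om_bg[k]
        P <- codon_probmat(egs[[match(w, omegas)]], t_e)
        idx <- which(site_class == k)
        if (!length(idx)) next
        par_states <- states[par, idx]
        states[chd, idx] <- vapply(par_states, function(s)
          sample.int(61, 1, prob = P[s, ]), 0L)
      }
    }
    aln <- apply(states[seq_len(pt$ntip), , drop = FALSE], 1, function(r)
      paste(cs$codons[r], collapse = ""))
    names(aln) <- pt$tree$tip.label
    labels <- if (regime$type == "branch_site")
      c("0", "1", "2a", "2b")[site_class] else site_class
    list(alignment = aln, site_class = labels, tree = tree, regime = regime,
         kappa = kappa, pi = pi)
  })
}

# Expected NG86 (Ks, Ka) between `codon_idx` start codons and their images
# after time t of a synonymous-biased (omega = 0) GY94 walk.
expected_ng86_at_t <- function(codon_idx, eg, t) {
  P <- codon_probmat(eg, t)
  sites <- ng86_site_counts()
  pc <- ng86_pair_counts()
  S1 <- sum(sites[codon_idx, "S"])
  N1 <- sum(sites[codon_idx, "N"])
  Pm <- P[codon_idx, , drop = FALSE]
  ES2 <- sum(Pm %*% sites[, "S"])
  EN2 <- sum(Pm %*% sites[, "N"])
  ESd <- sum(rowSums(Pm * pc$Sd[codon_idx, , drop = FALSE]))
  ENd <- sum(rowSums(Pm * pc$Nd[codon_idx, , drop = FALSE]))
  S <- (S1 + ES2) / 2
  N <- (N1 + EN2) / 2
  ps <- ESd / S
  pn <- ENd / N
  list(ps = ps, pn = pn,
       ks = if (ps < 0.75) -0.75 * log(1 - 4 * ps / 3) else Inf,
       ka = if (pn < 0.75) -0.75 * log(1 - 4 * pn / 3) else Inf)
}

#' Evolve a copy of a CDS to a target synonymous divergence
#'
#' Mutates `cds` under a synonymous-only GY94 process (omega = 0) for a time
#' calibrated numerically so that the *expected* NG86 Ks estimate between the
#' original and the copy equals `target_ks`.  Calibration is against the
#' estimator actually used downstream, not the raw substitution count.
#'
#' @param cds in-frame CDS without internal stops.
#' @param target_ks desired expected Ks (>= 0).
#' @param seed integer seed.
#' @param kappa transition/transversion ratio of the mutation process.
#' @return the mutated CDS string, with attribute `"t"` (calibrated branch
#'   length in unscaled GY94 time units).
#' @export
evolve_pair_to_ks <- function(cds, target_ks, seed = 1, kappa = 2) {
  stopifnot(target_ks >= 0)
  cs <- codon_states()
  idx <- match(split_codons(toupper(cds)), cs$codons)
  if (anyNA(idx)) stop("cds must be in-frame sense codons without stops")
  if (target_ks == 0) return(structure(cds, t = 0))
  if (target_ks >= -0.75 * log(1 / 4) * 2)   # far beyond any attainable Ks
    stop("saturation: target Ks ", target_ks, " is not attainable ",
         "(Jukes-Cantor correction undefined)")
  eg <- codon_eigen(kappa, 0, rep(1 / 61, 61))
  f <- function(t) expected_ng86_at_t(idx, eg, t)$ks - target_ks
  hi <- 1
  while (f(hi) < 0 && hi < 4096) hi <- hi * 2
  if (f(hi) < 0)
    stop("saturation: target Ks ", target_ks, " exceeds the attainable ",
         "synonymous divergence of this process")
  t_star <- uniroot(f, c(0, hi), tol = 1e-8)$root
  P <- codon_probmat(eg, t_star)
  with_seed(seed, {
    new_idx <- vapply(idx, function(s) sample.int(61, 1, prob = P[s, ]), 0L)
    structure(paste(cs$codons[new_idx], collapse = ""), t = t_star)
  })
}
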