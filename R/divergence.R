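# Type-I and Type-II functional divergence between paralogous clusters,
# following the two-state rate-shift framework: with probability theta a
# site's evolutionary rate (Type I) or physicochemical state (Type II) is
# cluster-specific rather than shared.

#' Minimum-change substitution counts per alignment site within a cluster
#'
#' Fitch parsimony on the subtree induced by the cluster's leaves; gaps and
#' ambiguity codes are treated as missing (they never force a change).
#'
#' @param aln named character vector: equal-length amino-acid alignment.
#' @param tree `phylo` containing the cluster leaves.
#' @param leaves cluster leaf names (>= 3).
#' @return integer vector of per-site minimum substitution counts.
#' @export
site_substitution_counts <- function(aln, tree, leaves) {
  if (length(leaves) < 3) stop("cluster must have >= 3 sequences")
  if (!all(leaves %in% names(aln)))
    stop("alignment missing cluster leaves: ",
         paste(setdiff(leaves, names(aln)), collapse = ", "))
  if (!all(leaves %in% tree$tip.label))
    stop("tree missing cluster leaves")
  sub <- ape::keep.tip(tree, leaves)
  sub <- ape::reorder.phylo(sub, "postorder")
  m <- do.call(rbind, strsplit(toupper(aln[sub$tip.label]), ""))
  ntip <- nrow(m)
  nsite <- ncol(m)
  miss <- !(m %in% c(LETTERS[-c(2, 10, 15, 21, 24, 26)]))  # 20 aa letters
  dim(miss) <- dim(m)
  counts <- integer(nsite)
  nnode <- ntip + sub$Nnode
  # children grouped per internal node; parents appear in postorder
  kids <- split(sub$edge[, 2], sub$edge[, 1])
  ord <- unique(sub$edge[, 1])
  for (s in seq_len(nsite)) {
    sets <- vector("list", nnode)
    for (t in seq_len(ntip))
      sets[[t]] <- if (miss[t, s]) character(0) else m[t, s]
    for (p in ord) {
      cur <- NULL
      for (k in kids[[as.character(p)]]) {
        kset <- sets[[k]]
        if (!length(kset)) next             # missing: no constraint
        if (is.null(cur)) {
          cur <- kset
        } else {
          inter <- intersect(cur, kset)
          if (length(inter)) {
            cur <- inter
          } else {
            cur <- union(cur, kset)
            counts[s] <- counts[s] + 1L
          }
        }
      }
      sets[[p]] <- if (is.null(cur)) character(0) else cur
    }
  }
  counts
}

#' Build a cluster pair for functional-divergence estimation
#'
#' @param aln amino-acid alignment (named, equal length).
#' @param tree `phylo` covering both clusters.
#' @param cluster1,cluster2 disjoint leaf sets (>= 3 each).
#' @return object of class `cluster_pair` holding per-site substitution
#'   counts and Poisson intensity scales (`d1`, `d2`, the mean per-site
#'   counts, a method-of-moments calibration since site rates average 1).
#' @export
cluster_pair <- function(aln, tree, cluster1, cluster2) {
  if (length(intersect(cluster1, cluster2)))
    stop("clusters must be disjoint")
  x1 <- site_substitution_counts(aln, tree, cluster1)
  x2 <- site_substitution_counts(aln, tree, cluster2)
  structure(list(x1 = x1, x2 = x2, d1 = mean(x1), d2 = mean(x2),
                 aln = aln, tree = tree,
                 cluster1 = cluster1, cluster2 = cluster2),
            class = "cluster_pair")
}

# Poisson-gamma (negative-binomial) site likelihoods of the two-state model.
# shared: one gamma(alpha, alpha) rate drives both clusters' Poisson counts;
# independent: each cluster draws its own rate.
theta1_loglik_parts <- function(x1, x2, d1, d2, alpha) {
  lg <- function(x, d) {
    # NB(x; size = alpha, mu = d): integral of Pois(x; d l) Gamma(l; a, a)
    dnbinom(x, size = alpha, mu = d, log = TRUE)
  }
  ind <- lg(x1, d1) + lg(x2, d2)
  sh <- lgamma(alpha + x1 + x2) - lgamma(alpha) - lfactorial(x1) -
    lfactorial(x2) + alpha * log(alpha) + x1 * log(d1 + (d1 == 0)) +
    x2 * log(d2 + (d2 == 0)) -
    (alpha + x1 + x2) * log(alpha + d1 + d2)
  list(shared = sh, independent = ind)
}

#' Estimate the Type-I functional divergence coefficient
#'
#' Maximum-likelihood fit of the two-state rate model: with probability
#' 1-theta a site's rate is a single gamma(alpha, alpha) draw shared by both
#' clusters (Poisson counts in each); with probability theta the two
#' clusters draw independent rates.  The gamma integrals are evaluated in
#' closed form (negative binomial), so no rate discretization is needed.
#' The LRT against theta = 0 uses chi-squared with 1 df.
#'
#' @param pair a [cluster_pair()], or a list with elements `x1`, `x2`
#'   (per-site counts) and optional `d1`, `d2` (intensity scales; default
#'   mean counts).
#' @return object of class `theta_fit` with `theta`, `alpha`, `se`,
#'   `lnL_alt`, `lnL_null`, `lrt` (statistic), `p_value`, and the inputs.
#' @export
estimate_theta1 <- function(pair) {
  x1 <- pair$x1; x2 <- pair$x2
  d1 <- pair$d1 %||% mean(x1)
  d2 <- pair$d2 %||% mean(x2)
  if (d1 == 0 && d2 == 0)
    return(structure(list(type = "I", theta = 0, alpha = NA_real_,
                          se = NA_real_, lnL_alt = 0, lnL_null = 0,
                          lrt = 0, p_value = 1, degenerate = TRUE,
                          x1 = x1, x2 = x2, d1 = d1, d2 = d2),
                     class = "theta_fit"))
  nll <- function(par) {
    th <- logistic(par[1]) * 0.999
    al <- exp(par[2])
    parts <- theta1_loglik_parts(x1, x2, d1, d2, al)
    mx <- pmax(parts$shared, parts$independent)
    -sum(mx + log((1 - th) * exp(parts$shared - mx) +
                    th * exp(parts$independent - mx)))
  }
  nll0 <- function(la) {
    parts <- theta1_loglik_parts(x1, x2, d1, d2, exp(la))
    -sum(parts$shared)
  }
  o0 <- optim(log(1), nll0, method = "Brent", lower = -8, upper = 8)
  o <- optim(c(0, o0$par), nll, method = "L-BFGS-B",
             lower = c(-12, -8), upper = c(12, 8))
  ob <- optim(c(-6, o0$par), nll, method = "L-BFGS-B",
              lower = c(-12, -8), upper = c(12, 8))
  if (ob$value < o$value) o <- ob
  theta <- logistic(o$par[1]) * 0.999
  alpha <- exp(o$par[2])
  if (-o$value < -o0$value) {        # theta = 0 boundary is in the model
    o$value <- o0$value
    theta <- 0
    alpha <- exp(o0$par)
  }
  se <- tryCatch({
    H <- optimHess(o$par, nll)
    # delta method back to the theta scale
    V <- solve(H)
    dth <- 0.999 * logistic(o$par[1]) * (1 - logistic(o$par[1]))
    sqrt(pmax(0, V[1, 1])) * dth
  }, error = function(e) NA_real_)
  lnL_alt <- -o$value
  lnL_null <- -o0$value
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  structure(list(type = "I", theta = theta, alpha = alpha, se = se,
                 lnL_alt = lnL_alt, lnL_null = lnL_null, lrt = stat,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 degenerate = FALSE, x1 = x1, x2 = x2, d1 = d1, d2 = d2),
            class = "theta_fit")
}

#' Amino-acid property partition for Type-II divergence
#'
#' Loads the shipped charge/polarity partition (nonpolar, polar, acidic,
#' basic); an amino-acid replacement is *radical* when it crosses classes.
#'
#' @param path optional TSV with columns `aa`, `class`.
#' @return named character vector: class per amino acid.
#' @export
load_aa_classes <- function(path = system.file("extdata",
                                               "aa_property_classes.tsv",
                                               package = "famevol")) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(d$class, d$aa)
}

# Fraction of unordered distinct amino-acid pairs that are radical under a
# partition: the background probability that a fixed difference is radical.
radical_fraction <- function(classes) {
  aa <- names(classes)
  n <- length(aa)
  tot <- 0; rad <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (classes[i] != classes[j]) rad <- rad + 1
  }
  if (tot == 0) 0 else rad / tot
}

# Site categories for Type-II estimation: conserved in both clusters and
# identical (A), conserved with a conservative difference (B), conserved
# with a radical difference (C), or variable in either cluster (D).
type2_categories <- function(aln, cluster1, cluster2, classes) {
  sub <- function(leaves) do.call(rbind, strsplit(toupper(aln[leaves]), ""))
  m1 <- sub(cluster1); m2 <- sub(cluster2)
  nsite <- ncol(m1)
  cat_ <- character(nsite)
  aa_ok <- names(classes)
  for (s in seq_len(nsite)) {
    r1 <- unique(m1[, s]); r1 <- r1[r1 %in% aa_ok]
    r2 <- unique(m2[, s]); r2 <- r2[r2 %in% aa_ok]
    if (length(r1) != 1 || length(r2) != 1) {
      cat_[s] <- "D"
    } else if (r1 == r2) {
      cat_[s] <- "A"
    } else if (classes[[r1]] != classes[[r2]]) {
      cat_[s] <- "C"
    } else {
      cat_[s] <- "B"
    }
  }
  cat_
}

#' Estimate the Type-II functional divergence coefficient
#'
#' Count-category formulation (a deliberate simplification of the full
#' covarion treatment, stated as such): each site is either Type-II
#' divergent (probability theta2) -- conserved within both clusters but
#' fixed for a *radical* difference -- or follows the background, where a
#' fixed difference is radical with the partition's pair-level probability
#' rho0.  Categories: A conserved-identical, B conserved-conservative
#' difference, C conserved-radical difference, D variable-in-either.  The
#' model P(C) = theta + (1-theta) pi rho0, P(B) = (1-theta) pi (1-rho0),
#' P(A or D) = (1-theta)(1-pi) is maximized over (theta, pi); the LRT
#' against theta = 0 uses chi-squared with 1 df.
#'
#' @param pair a [cluster_pair()] (or list with `aln`, `cluster1`,
#'   `cluster2`).
#' @param classes amino-acid property partition from [load_aa_classes()].
#' @return a `theta_fit` of type II, with the per-site categories attached.
#' @export
estimate_theta2 <- function(pair, classes = load_aa_classes()) {
  cat_ <- type2_categories(pair$aln, pair$cluster1, pair$cluster2, classes)
  rho0 <- radical_fraction(classes)
  nC <- sum(cat_ == "C"); nB <- sum(cat_ == "B")
  nO <- sum(cat_ %in% c("A", "D"))
  n <- nC + nB + nO
  loglik <- function(th, pi_) {
    pc <- th + (1 - th) * pi_ * rho0
    pb <- (1 - th) * pi_ * (1 - rho0)
    po <- (1 - th) * (1 - pi_)
    if (pc <= 0 && nC > 0) return(-Inf)
    nC * log(pc + (nC == 0)) + nB * log(pb + (nB == 0)) +
      nO * log(po + (nO == 0))
  }
  if (rho0 == 0 || nC == 0) {
    # no radical difference is definable/observed: theta2 = 0 by construction
    pi_hat <- (nB + nC) / max(1, n)
    l0 <- loglik(0, pi_hat)
    return(structure(list(type = "II", theta = 0, se = NA_real_,
                          lnL_alt = l0, lnL_null = l0, lrt = 0, p_value = 1,
                          pi = pi_hat, rho0 = rho0, categories = cat_,
                          degenerate = rho0 == 0),
                     class = "theta_fit"))
  }
  nll <- function(par) -loglik(logistic(par[1]) * 0.999, logistic(par[2]))
  nll0 <- function(par) -loglik(0, logistic(par))
  o0 <- optim(0, nll0, method = "Brent", lower = -12, upper = 12)
  o <- optim(c(-2, o0$par), nll, method = "L-BFGS-B",
             lower = c(-12, -12), upper = c(12, 12))
  theta <- logistic(o$par[1]) * 0.999
  se <- tryCatch({
    H <- optimHess(o$par, nll)
    V <- solve(H)
    dth <- 0.999 * logistic(o$par[1]) * (1 - logistic(o$par[1]))
    sqrt(pmax(0, V[1, 1])) * dth
  }, error = function(e) NA_real_)
  lnL_alt <- -o$value
  lnL_null <- -o0$value
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  structure(list(type = "II", theta = theta, se = se, lnL_alt = lnL_alt,
                 lnL_null = lnL_null, lrt = stat,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 pi = logistic(o$par[2]), rho0 = rho0, categories = cat_,
                 degenerate = FALSE),
            class = "theta_fit")
}

#' @export
print.theta_fit <- function(x, ...) {
  cat(sprintf("Type-%s functional divergence\n", x$type))
  cat(sprintf("  theta = %.4f (se %.4f)   lnL_alt = %.3f  lnL_null = %.3f\n",
              x$theta, x$se, x$lnL_alt, x$lnL_null))
  cat(sprintf("  LRT (theta = 0): 2dlnL = %.3f, p = %.4g\n", x$lrt,
              x$p_value))
  invisible(x)
}

#' @export
coef.theta_fit <- function(object, ...) {
  out <- c(theta = object$theta)
  if (!is.null(object$alpha)) out <- c(out, alpha = object$alpha)
  if (!is.null(object$pi)) out <- c(out, pi = object$pi)
  out
}

#' @export
logLik.theta_fit <- function(object, ...) {
  structure(object$lnL_alt, df = 2, class = "logLik")
}

#' Posterior probability per site of the divergent state
#'
#' Empirical-Bayes posteriors: for Type I, the posterior that a site's rates
#' are cluster-independent; for Type II, the posterior that a category-C
#' site belongs to the divergent state.  Sites above `cutoff` are flagged as
#' candidate critical residues.
#'
#' @param fit a `theta_fit` from [estimate_theta1()] or
#'   [estimate_theta2()].
#' @param cutoff flagging threshold (default 0.8).
#' @return data.frame `site`, `qk`, `flagged`.
#' @export
site_qk <- function(fit, cutoff = 0.8) {
  if (fit$type == "I") {
    if (fit$theta == 0 || isTRUE(fit$degenerate)) {
      qk <- rep(0, length(fit$x1))
    } else {
      parts <- theta1_loglik_parts(fit$x1, fit$x2, fit$d1, fit$d2,
                                   fit$alpha)
      num <- fit$theta * exp(parts$independent)
      qk <- num / (num + (1 - fit$theta) * exp(parts$shared))
    }
  } else {
    qk <- numeric(length(fit$categories))
    if (fit$theta > 0) {
      pc <- fit$theta + (1 - fit$theta) * fit$pi * fit$rho0
      qk[fit$categories == "C"] <- fit$theta / pc
    }
  }
  data.frame(site = seq_along(qk), qk = qk, flagged = qk > cutoff)
}
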