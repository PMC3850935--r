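# Maximum-likelihood fitting of GY94 codon models: site models M0, M3 (K
# discrete classes), M7 (beta), M8 (beta & omega) and branch-site model A
# (alternative and null variants), with LRTs and NEB/BEB site posteriors.

OMEGA_MAX <- 999           # omega upper bound; boundary hits are flagged

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# Median-of-category discretization of beta(p, q) into equal-probability
# bins.  qbeta's accuracy warning at extreme shapes is irrelevant here: any
# monotone representative inside each bin serves the discretization.
beta_categories <- function(ncat, p, q) {
  suppressWarnings(qbeta((seq_len(ncat) - 0.5) / ncat, p, q))
}

# Model descriptors: unconstrained parameter vector <-> class structure.
model_spec <- function(model, K = 3, ncat = 10, null = FALSE) {
  lk_b <- c(log(0.1), log(50))
  switch(model,
    M0 = list(
      nfree = 2,
      init = function() c(log(2), log(0.4)),
      lower = c(lk_b[1], log(1e-6)), upper = c(lk_b[2], log(OMEGA_MAX)),
      classes = function(th) {
        list(kappa = exp(th[1]),
             cls = class_structure(1, exp(th[2])),
             params = list(omega = exp(th[2])))
      }),
    M3 = list(
      nfree = 1 + (K - 1) + K,
      init = function() c(log(2), rep(0, K - 1),
                          log(0.05), rep(log(0.5), K - 1)),
      lower = c(lk_b[1], rep(-12, K - 1), log(1e-6), rep(-12, K - 1)),
      upper = c(lk_b[2], rep(12, K - 1), rep(log(OMEGA_MAX), K)),
      classes = function(th) {
        a <- if (K > 1) c(0, th[2:K]) else 0
        w <- exp(a - max(a)); w <- w / sum(w)
        om <- cumsum(exp(th[(K + 1):(2 * K)]))
        om <- pmin(om, OMEGA_MAX)
        list(kappa = exp(th[1]), cls = class_structure(w, om),
             params = list(p = w, omega = om))
      }),
    M7 = list(
      nfree = 3,
      init = function() c(log(2), log(0.5), log(1.5)),
      lower = c(lk_b[1], log(0.005), log(0.005)),
      upper = c(lk_b[2], log(99), log(99)),
      classes = function(th) {
        p <- exp(th[2]); q <- exp(th[3])
        om <- beta_categories(ncat, p, q)
        list(kappa = exp(th[1]),
             cls = class_structure(rep(1 / ncat, ncat), om),
             params = list(p = p, q = q))
      }),
    M8 = list(
      nfree = 5,
      init = function() c(log(2), logit(0.9), log(0.5), log(1.5), log(0.5)),
      lower = c(lk_b[1], -12, log(0.005), log(0.005), log(1e-4)),
      upper = c(lk_b[2], 12, log(99), log(99), log(OMEGA_MAX - 1)),
      classes = function(th) {
        p0 <- logistic(th[2]); p <- exp(th[3]); q <- exp(th[4])
        ws <- 1 + exp(th[5])
        om <- c(beta_categories(ncat, p, q), ws)
        w <- c(rep(p0 / ncat, ncat), 1 - p0)
        list(kappa = exp(th[1]), cls = class_structure(w, om),
             params = list(p0 = p0, p = p, q = q, omega_s = ws))
      }),
    bsA = {
      nf <- if (null) 4 else 5
      list(
        nfree = nf,
        init = function() {
          base <- c(log(2), logit(0.8), logit(0.85), logit(0.1))
          if (null) base else c(base, log(1.5))
        },
        lower = c(lk_b[1], -12, -12, -12, if (!null) log(1e-4)),
        upper = c(lk_b[2], 12, 12, logit(1 - 1e-8),
                  if (!null) log(OMEGA_MAX - 1)),
        classes = function(th) {
          s <- logistic(th[2]); r <- logistic(th[3])
          w0 <- logistic(th[4])
          w2 <- if (null) 1 else 1 + exp(th[5])
          w <- c(s * r, s * (1 - r), (1 - s) * r, (1 - s) * (1 - r))
          list(kappa = exp(th[1]),
               cls = class_structure(w, om_bg = c(w0, 1, w0, 1),
                                     om_fg = c(w0, 1, w2, w2)),
               params = list(p0 = w[1], p1 = w[2], p2a = w[3], p2b = w[4],
                             omega0 = w0, omega2 = w2))
        })
    },
    stop("unknown model: ", model))
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits one of the GY94 site models (M0 one-ratio, M3 discrete, M7 beta,
#' M8 beta & omega) or branch-site model A to a codon alignment on a fixed
#' tree, by bounded quasi-Newton maximisation with multiple random starts.
#'
#' @param aln named character vector of aligned in-frame CDS, or the list
#'   returned by [sim_codon_alignment()].
#' @param tree rooted `phylo` with branch lengths (held fixed, or globally
#'   rescaled when `branch_lengths = "scale"`).
#' @param model one of `"M0"`, `"M3"`, `"M7"`, `"M8"`, `"bsA"`.
#' @param null for `"bsA"`: fit the null variant with omega2 fixed at 1.
#' @param foreground foreground branch labels (required for `"bsA"`).
#' @param freqs `"uniform"` or `"F3x4"` codon frequencies (F3x4 is estimated
#'   from the data).
#' @param K number of discrete classes for M3.
#' @param ncat number of beta categories for M7/M8.
#' @param branch_lengths `"fixed"` (default) or `"scale"` (estimate a single
#'   multiplier of all supplied branch lengths).
#' @param n_starts number of optimizer starts (first from fixed defaults,
#'   the rest randomly jittered).
#' @param seed seed for the random starts.
#' @param control passed to [stats::optim()] (method `"L-BFGS-B"`).
#' @return an object of class `codon_fit` with `print`, `summary`, `coef`
#'   and `logLik` methods; see also [codon_lrt()] and [site_posteriors()].
#' @examples
#' tr <- sim_tree(6, "birth_death", seed = 1)
#' s <- sim_codon_alignment(tr, 120, regime_m0(0.3), kappa = 2, seed = 2)
#' fit_codon_model(s, tr, "M0", n_starts = 1)
#' @export
fit_codon_model <- function(aln, tree, model = c("M0", "M3", "M7", "M8",
                                                 "bsA"),
                            null = FALSE, foreground = NULL,
                            freqs = c("uniform", "F3x4"), K = 3, ncat = 10,
                            branch_lengths = c("fixed", "scale"),
                            n_starts = 3, seed = 1, control = list()) {
  model <- match.arg(model)
  freqs <- match.arg(freqs)
  branch_lengths <- match.arg(branch_lengths)
  if (is.list(aln) && !is.null(aln$alignment)) aln <- aln$alignment
  if (model == "bsA" && is.null(foreground))
    stop("branch-site model requires a foreground branch set")
  pt <- prep_tree(tree, if (model == "bsA") foreground else NULL)
  if (!all(pt$tree$tip.label %in% names(aln)))
    stop("alignment is missing sequences for tips: ",
         paste(setdiff(pt$tree$tip.label, names(aln)), collapse = ", "))
  m <- codon_index_matrix(aln[pt$tree$tip.label])
  pat <- site_patterns(m)
  pi <- if (freqs == "F3x4") f3x4_frequencies(aln) else rep(1 / 61, 61)

  ms <- model_spec(model, K = K, ncat = ncat, null = null)
  scale_par <- branch_lengths == "scale"
  nfree <- ms$nfree + scale_par
  base_elen <- pt$elen

  negll <- function(th) {
    cc <- ms$classes(th)
    if (scale_par) pt$elen <- base_elen * exp(th[length(th)])
    lik <- site_class_liks(pat, pt, cc$kappa, cc$cls, pi)
    mix <- as.vector(lik %*% cc$cls$weights)
    if (any(mix <= 0) || any(!is.finite(mix))) return(1e10)
    -sum(pat$weight * log(mix))
  }

  starts <- list(c(ms$init(), if (scale_par) 0))
  if (n_starts > 1) {
    jit <- child_seeds(seed, n_starts - 1)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- with_seed(jit[i],
        starts[[1]] + rnorm(nfree, 0, 0.75))
  }
  lower <- c(ms$lower, if (scale_par) log(0.05))
  upper <- c(ms$upper, if (scale_par) log(20))
  ctrl <- modifyList(list(factr = 1e7, maxit = 300), control)

  best <- NULL
  conv <- FALSE
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    o <- tryCatch(optim(st, negll, method = "L-BFGS-B", lower = lower,
                        upper = upper, control = ctrl),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed")

  cc <- ms$classes(best$par)
  if (scale_par) pt$elen <- base_elen * exp(best$par[length(best$par)])
  lik <- site_class_liks(pat, pt, cc$kappa, cc$cls, pi)
  boundary <- any(abs(unlist(cc$params)[grepl("omega", names(unlist(cc$params)))] -
                      OMEGA_MAX) < 1e-6)
  fit <- list(model = model, null = null, logLik = -best$value,
              kappa = cc$kappa, params = cc$params, classes = cc$cls,
              pi = pi, freqs = freqs, nfree = nfree, ncat = ncat, K = K,
              foreground = foreground, tree = tree,
              branch_scale = if (scale_par) exp(best$par[length(best$par)])
                             else 1,
              converged = conv && best$convergence == 0,
              boundary = boundary,
              site_lik = lik, pat = pat, pt = pt,
              n_sites = ncol(m), n_taxa = nrow(m),
              optim = best[c("value", "counts", "convergence")],
              n_starts = n_starts, seed = seed)
  class(fit) <- "codon_fit"
  if (!fit$converged)
    warning("optimizer did not report convergence for model ", model)
  fit
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$logLik, df = object$nfree, class = "logLik")
}

#' @export
coef.codon_fit <- function(object, ...) {
  p <- unlist(object$params)
  c(kappa = object$kappa, p)
}

#' @export
print.codon_fit <- function(x, ...) {
  tag <- if (x$model == "bsA")
    paste0("branch-site model A", if (x$null) " (null, omega2 = 1)") else
    x$model
  cat(sprintf("Codon model %s  (%d taxa, %d codons, %s frequencies)\n",
              tag, x$n_taxa, x$n_sites, x$freqs))
  cat(sprintf("  lnL = %.4f   kappa = %.3f%s%s\n", x$logLik, x$kappa,
              if (x$converged) "" else "   [NOT CONVERGED]",
              if (x$boundary) "   [omega at bound]" else ""))
  p <- unlist(x$params)
  cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.codon_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  site classes: %s\n",
              paste(sprintf("w=%.3g (omega_bg=%.3g, omega_fg=%.3g)",
                            object$classes$weights, object$classes$om_bg,
                            object$classes$om_fg), collapse = "; ")))
  invisible(object)
}

#' Likelihood-ratio test between nested codon model fits
#'
#' Supported pairs: M0 vs M3, M7 vs M8, branch-site A null vs alternative.
#' The statistic 2(lnL_alt - lnL_null) is floored at zero and referred to a
#' chi-squared distribution; the branch-site test uses chi2(1), the
#' conservative variant of the 50:50 boundary mixture.
#'
#' @param fit_null,fit_alt `codon_fit` objects for the nested pair.
#' @param df degrees of freedom; inferred from the model pair when `NULL`.
#' @return list with `lnL_null`, `lnL_alt`, `two_delta_lnL`, `df`,
#'   `p_value`.
#' @export
codon_lrt <- function(fit_null, fit_alt, df = NULL) {
  pair <- paste(fit_null$model, fit_alt$model)
  ok <- (pair == "M0 M3") || (pair == "M7 M8") ||
    (pair == "bsA bsA" && fit_null$null && !fit_alt$null)
  if (!ok)
    stop("non-nested or unsupported model pair: ", pair)
  if (is.null(df)) df <- fit_alt$nfree - fit_null$nfree
  stat <- max(0, 2 * (fit_alt$logLik - fit_null$logLik))
  list(lnL_null = fit_null$logLik, lnL_alt = fit_alt$logLik,
       two_delta_lnL = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Class indices of the positively selected component of a fit.
positive_classes <- function(fit) {
  cls <- fit$classes
  if (fit$model == "bsA") {
    if (fit$null || fit$params$omega2 <= 1)
      stop("fit has no positively selected class")
    return(3:4)
  }
  pos <- which(cls$om_bg > 1)
  if (!length(pos))
    stop("fit has no positively selected class (no omega > 1)")
  pos
}

#' Posterior probabilities that sites belong to the positive-selection class
#'
#' NEB plugs the maximum-likelihood estimates into Bayes' rule.  BEB
#' (available for M8 and branch-site A) integrates the mixture proportions
#' and the positive-class omega over a uniform 10-point grid per dimension,
#' holding the remaining parameters at their MLEs.
#'
#' @param fit a converged `codon_fit`.
#' @param method `"NEB"` or `"BEB"`.
#' @return data.frame with `site` (alignment codon index), `prob`, `method`
#'   and `star` (`"*"` above 0.95, `"**"` above 0.99).
#' @export
site_posteriors <- function(fit, method = c("NEB", "BEB")) {
  method <- match.arg(method)
  pos <- positive_classes(fit)
  if (method == "NEB" || fit$model == "M3" || fit$model == "M0") {
    w <- fit$classes$weights
    mix <- as.vector(fit$site_lik %*% w)
    pp <- as.vector(fit$site_lik[, pos, drop = FALSE] %*% w[pos]) / mix
    method <- "NEB"
  } else if (fit$model == "M8") {
    pp <- beb_m8(fit)
  } else {
    pp <- beb_bsa(fit)
  }
  prob <- pp[fit$pat$map]
  data.frame(site = seq_along(prob), prob = prob, method = method,
             star = ifelse(prob > 0.99, "**", ifelse(prob > 0.95, "*", "")),
             stringsAsFactors = FALSE)
}

# BEB over (p0, omega_s) for M8; beta(p, q) and kappa at their MLEs.
beb_m8 <- function(fit, ngrid = 10) {
  ncat <- fit$ncat
  f_beta <- rowMeans(fit$site_lik[, seq_len(ncat), drop = FALSE])
  p0g <- (seq_len(ngrid) - 0.5) / ngrid
  wsg <- 1 + (seq_len(ngrid) - 0.5)
  f_pos <- vapply(wsg, function(ws) {
    site_class_liks(fit$pat, fit$pt, fit$kappa, mixed_norm_cls(fit, ws),
                    fit$pi)[, length(fit$classes$weights)]
  }, numeric(nrow(fit$site_lik)))
  lw <- matrix(NA_real_, ngrid, ngrid)
  contrib <- array(NA_real_, c(nrow(fit$site_lik), ngrid, ngrid))
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
    mixl <- p0g[i] * f_beta + (1 - p0g[i]) * f_pos[, j]
    lw[i, j] <- sum(fit$pat$weight * log(mixl))
    contrib[, i, j] <- (1 - p0g[i]) * f_pos[, j] / mixl
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  pp <- numeric(nrow(fit$site_lik))
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid))
    pp <- pp + w[i, j] * contrib[, i, j]
  pp
}

# Recompute the positive-class site likelihoods with omega_s replaced,
# keeping the model's normalization convention.
mixed_norm_cls <- function(fit, ws) {
  cls <- fit$classes
  om_bg <- cls$om_bg; om_fg <- cls$om_fg
  om_bg[length(om_bg)] <- ws
  om_fg[length(om_fg)] <- ws
  class_structure(cls$weights, om_bg, om_fg)
}

# BEB over (s, r, omega2) for branch-site model A; omega0, kappa at MLEs.
beb_bsa <- function(fit, ngrid = 10) {
  sg <- (seq_len(ngrid) - 0.5) / ngrid
  rg <- sg
  w2g <- 1 + (seq_len(ngrid) - 0.5)
  w0 <- fit$params$omega0
  f01 <- fit$site_lik[, 1:2, drop = FALSE]
  f2 <- lapply(w2g, function(w2) {
    cls <- class_structure(fit$classes$weights, c(w0, 1, w0, 1),
                           c(w0, 1, w2, w2))
    site_class_liks(fit$pat, fit$pt, fit$kappa, cls, fit$pi)[, 3:4]
  })
  npat <- nrow(fit$site_lik)
  lws <- array(NA_real_, c(ngrid, ngrid, ngrid))
  pp <- numeric(npat)
  store <- array(NA_real_, c(npat, ngrid, ngrid, ngrid))
  for (a in seq_len(ngrid)) for (b in seq_len(ngrid)) for (l in seq_len(ngrid)) {
    s <- sg[a]; r <- rg[b]
    w <- c(s * r, s * (1 - r), (1 - s) * r, (1 - s) * (1 - r))
    mixl <- f01 %*% w[1:2] + f2[[l]] %*% w[3:4]
    lws[a, b, l] <- sum(fit$pat$weight * log(mixl))
    store[, a, b, l] <- (f2[[l]] %*% w[3:4]) / mixl
  }
  wgt <- exp(lws - max(lws)); wgt <- wgt / sum(wgt)
  for (a in seq_len(ngrid)) for (b in seq_len(ngrid)) for (l in seq_len(ngrid))
    pp <- pp + wgt[a, b, l] * store[, a, b, l]
  pp
}
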