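# Independent brute-force oracles.  These are written from first principles
# (own genetic-code handling, explicit enumeration) and deliberately share no
# code with the package internals they check.

.oracle_codons <- local({
  nt <- c("A", "C", "G", "T")
  all64 <- apply(expand.grid(nt, nt, nt)[, 3:1], 1, paste, collapse = "")
  all64 <- sort(all64)
  gc <- Biostrings::GENETIC_CODE[all64]
  list(sense = all64[gc != "*"], aa = gc)
})

oracle_aa <- function(codon) unname(.oracle_codons$aa[codon])

# --- NG86 oracle ------------------------------------------------------------

# synonymous site count of one codon: fraction of the nine point changes that
# are synonymous (stop-creating changes count as nonsynonymous)
oracle_syn_sites <- function(codon) {
  nt <- c("A", "C", "G", "T")
  v <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(nt, v[pos])) {
    w <- v; w[pos] <- b
    mut <- paste(w, collapse = "")
    if (oracle_aa(mut) != "*" && oracle_aa(mut) == oracle_aa(codon))
      s <- s + 1 / 3
  }
  s
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# (Sd, Nd) for a codon pair by explicit enumeration of all substitution
# orderings; orderings passing through a stop are dropped (all kept, with
# stop steps nonsynonymous, if every ordering is blocked)
oracle_pair_diffs <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1]]
  v2 <- strsplit(c2, "")[[1]]
  dif <- which(v1 != v2)
  if (!length(dif)) return(c(0, 0))
  res <- NULL
  for (ord in perms(dif)) {
    cur <- v1; s <- 0; n <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- v2[pos]
      a1 <- oracle_aa(paste(cur, collapse = ""))
      a2 <- oracle_aa(paste(nxt, collapse = ""))
      if (a1 == "*" || a2 == "*") blocked <- TRUE
      if (a1 == a2 && a1 != "*") s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    res <- rbind(res, c(s, n, blocked))
  }
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(mean(res[ok, 1]), mean(res[ok, 2]))
}

oracle_ng86 <- function(x, y) {
  cx <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  cy <- substring(y, seq(1, nchar(y), 3), seq(3, nchar(y), 3))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(cx)) {
    s1 <- oracle_syn_sites(cx[i]); s2 <- oracle_syn_sites(cy[i])
    S <- S + (s1 + s2) / 2
    N <- N + (3 - s1 + 3 - s2) / 2
    d <- oracle_pair_diffs(cx[i], cy[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

# random pair of aligned CDS at moderate divergence (no stops)
random_cds_pair <- function(n_codons, p_mut = 0.15) {
  sense <- .oracle_codons$sense
  x <- sample(sense, n_codons, replace = TRUE)
  y <- vapply(x, function(cod) {
    if (runif(1) > p_mut) return(cod)
    repeat {
      v <- strsplit(cod, "")[[1]]
      k <- sample(1:3, sample(1:2, 1))
      v[k] <- sample(c("A", "C", "G", "T"), length(k), replace = TRUE)
      mut <- paste(v, collapse = "")
      if (oracle_aa(mut) != "*") return(mut)
    }
  }, "")
  list(x = paste(x, collapse = ""), y = paste(y, collapse = ""))
}

# --- likelihood oracle ------------------------------------------------------

# GY94 generator built independently (dense loops over codon strings)
oracle_gy94 <- function(kappa, omega, pi) {
  sense <- .oracle_codons$sense
  n <- length(sense)
  ts_pair <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  Q <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    v1 <- strsplit(sense[i], "")[[1]]
    v2 <- strsplit(sense[j], "")[[1]]
    dif <- which(v1 != v2)
    if (length(dif) != 1) next
    r <- pi[j]
    if (ts_pair(v1[dif], v2[dif])) r <- r * kappa
    if (oracle_aa(sense[i]) != oracle_aa(sense[j])) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# exhaustive likelihood: explicit sum over all internal-node codon
# assignments (vectorised over the assignment grid, but still a literal
# enumeration -- no pruning factorisation)
oracle_loglik <- function(aln, tree, kappa, omega, pi) {
  sense <- .oracle_codons$sense
  tr <- ape::reorder.phylo(tree, "postorder")
  Q <- oracle_gy94(kappa, omega, pi)
  P <- lapply(tr$edge.length, function(t)
    as.matrix(Matrix::expm(Q * t)))
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  root <- ntip + 1
  m <- do.call(rbind, lapply(tr$tip.label, function(l) {
    s <- aln[[l]]
    match(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)), sense)
  }))
  nsite <- ncol(m)
  grid <- as.matrix(expand.grid(rep(list(seq_along(sense)), nint)))
  ngrid <- nrow(grid)
  ll <- 0
  for (s in seq_len(nsite)) {
    state_of <- function(node) {
      if (node <= ntip) rep(m[node, s], ngrid) else grid[, node - ntip]
    }
    pr <- pi[state_of(root)]
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * P[[e]][cbind(state_of(tr$edge[e, 1]),
                              state_of(tr$edge[e, 2]))]
    ll <- ll + log(sum(pr))
  }
  ll
}

# --- Fitch oracle -----------------------------------------------------------

# minimum substitution count by enumerating every internal-node assignment
# over the states observed at the leaves
oracle_fitch <- function(tip_states, tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  states <- unique(tip_states[!is.na(tip_states)])
  if (length(states) <= 1) return(0L)
  nint <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(states), nint)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asg <- c(tip_states[tr$tip.label], grid[g, ])
    ch <- 0
    for (e in seq_len(nrow(tr$edge))) {
      a <- asg[tr$edge[e, 1]]; b <- asg[tr$edge[e, 2]]
      if (!is.na(a) && !is.na(b) && a != b) ch <- ch + 1
    }
    best <- min(best, ch)
  }
  as.integer(best)
}

# --- IUPAC scan oracle ------------------------------------------------------

iupac_sets <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_iupac_count <- function(seq, pattern, both_strands = TRUE) {
  match_at <- function(s, p, at) {
    for (k in seq_len(nchar(p))) {
      allowed <- strsplit(iupac_sets[[substr(p, k, k)]], "")[[1]]
      sub <- substr(s, at + k - 1, at + k - 1)
      subset <- strsplit(iupac_sets[[sub]], "")[[1]]
      if (!all(subset %in% allowed)) return(FALSE)
    }
    TRUE
  }
  rc <- function(p) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(comp[strsplit(p, "")[[1]]]), collapse = "")
  }
  L <- nchar(pattern)
  hits <- 0
  for (at in seq_len(nchar(seq) - L + 1)) {
    f <- match_at(seq, pattern, at)
    r <- both_strands && match_at(seq, rc(pattern), at)
    if (f || r) hits <- hits + 1
  }
  hits
}

# --- domain scan oracle -----------------------------------------------------

# all (heptapeptide, finger) pairings by direct index enumeration
oracle_domain_pairs <- function(protein, max_gap = 50) {
  v <- strsplit(protein, "")[[1]]
  n <- length(v)
  hepta <- c()
  for (i in seq_len(max(0, n - 6)))
    if (paste(v[i:(i + 6)], collapse = "") == "WRKYGQK")
      hepta <- c(hepta, i)
  fingers <- NULL
  for (i in seq_len(n)) {
    for (x1 in 4:5) for (x2 in 22:23) {
      e <- i + 1 + x1 + 1 + x2 + 2
      if (e > n) next
      if (v[i] == "C" && v[i + x1 + 1] == "C" && v[e - 2] == "H" &&
          v[e] == "H")
        fingers <- rbind(fingers, c(i, e, x1, x2, 1))
    }
    x1 <- 7; x2 <- 23
    e <- i + 1 + x1 + 1 + x2 + 2
    if (e <= n && v[i] == "C" && v[i + x1 + 1] == "C" && v[e - 2] == "H" &&
        v[e] == "C")
      fingers <- rbind(fingers, c(i, e, x1, x2, 2))
  }
  list(hepta = hepta, fingers = fingers)
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "G", "H",
                                           "K", "L", "N", "P", "Q", "R",
                                           "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
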