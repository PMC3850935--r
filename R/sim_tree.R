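# Random tree simulation for the synthetic-data generators.

balanced_newick <- function(labels) {
  n <- length(labels)
  if (n == 1) return(labels)
  h <- ceiling(n / 2)
  paste0("(", balanced_newick(labels[seq_len(h)]), ",",
         balanced_newick(labels[(h + 1):n]), ")")
}

#' Simulate a rooted binary tree with branch lengths
#'
#' @param n_taxa number of tips (>= 2).
#' @param shape `"birth_death"` (ape birth-death sampling), `"balanced"`
#'   (maximally balanced topology) or `"caterpillar"` (pectinate).
#' @param seed integer seed; the result is a pure function of
#'   `(n_taxa, shape, seed)`.
#' @param mean_brlen mean branch length (expected substitutions per codon)
#'   used to rescale/draw branch lengths.
#' @return rooted `phylo` with tips `t1..tn` and positive branch lengths.
#' @export
sim_tree <- function(n_taxa, shape = c("birth_death", "balanced",
                                       "caterpillar"),
                     seed = 1, mean_brlen = 0.15) {
  shape <- match.arg(shape)
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  with_seed(seed, {
    labels <- paste0("t", seq_len(n_taxa))
    if (shape == "birth_death" && n_taxa > 2) {
      tr <- ape::rphylo(n_taxa, birth = 1, death = 0.2)
      tr$tip.label <- labels
      tr$edge.length <- tr$edge.length * mean_brlen / mean(tr$edge.length)
      # guard against numerically zero branches
      tr$edge.length <- pmax(tr$edge.length, 1e-4)
    } else {
      nwk <- if (shape == "caterpillar" && n_taxa > 2)
        paste0(paste(rep("(", n_taxa - 1), collapse = ""), labels[1], ",",
               paste(labels[-1], collapse = "),"), ");")
      else paste0(balanced_newick(labels), ";")
      tr <- ape::read.tree(text = nwk)
      tr$edge.length <- runif(nrow(tr$edge), 0.5 * mean_brlen,
                              1.5 * mean_brlen)
    }
    tr
  })
}
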