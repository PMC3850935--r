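# End-to-end orchestration: classify -> duplication mapping -> Ks dating ->
# (optional) selection and divergence -> expression/promoters, with a
# family-level summary table.

#' Pipeline configuration
#'
#' Collects input paths and the analysis thresholds with their standard
#' defaults: 10 intervening genes for tandem arrays, a 100-kb anchor
#' window, 3 anchors minimum, Ks saturation cutoff 1.0, soybean clock rate
#' 6.1e-9, Qk cutoff 0.8, 1500-bp promoters.
#'
#' @param gff,cds,proteins,family input file paths (GFF3, CDS FASTA,
#'   protein FASTA, family id list -- one id per line).
#' @param expression optional expression TSV (genes x tissues).
#' @param promoters optional promoter FASTA.
#' @param catalog optional cis-element catalog TSV.
#' @param subgroup_refs optional labelled subgroup reference TSV.
#' @param lambda,max_intervening,window_kb,min_anchors,ks_cutoff,qk_cutoff
#'   analysis thresholds (defaults as above).
#' @param expressed_cutoff,peak_z expression breadth thresholds.
#' @param promoter_length expected promoter length in bp.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gff = NULL, cds = NULL, proteins = NULL,
                            family = NULL, expression = NULL,
                            promoters = NULL, catalog = NULL,
                            subgroup_refs = NULL,
                            lambda = 6.1e-9, max_intervening = 10,
                            window_kb = 100, min_anchors = 3,
                            ks_cutoff = 1.0, qk_cutoff = 0.8,
                            expressed_cutoff = 1.0, peak_z = 1.5,
                            promoter_length = 1500) {
  num <- c(lambda = lambda, max_intervening = max_intervening,
           window_kb = window_kb, min_anchors = min_anchors,
           ks_cutoff = ks_cutoff, qk_cutoff = qk_cutoff,
           expressed_cutoff = expressed_cutoff, peak_z = peak_z,
           promoter_length = promoter_length)
  if (any(num <= 0))
    stop("all numeric thresholds must be positive: ",
         paste(names(num)[num <= 0], collapse = ", "))
  structure(c(list(gff = gff, cds = cds, proteins = proteins,
                   family = family, expression = expression,
                   promoters = promoters, catalog = catalog,
                   subgroup_refs = subgroup_refs), as.list(num)),
            class = "pipeline_config")
}

require_inputs <- function(config, stage, fields) {
  miss <- fields[vapply(fields, function(f) is.null(config[[f]]), TRUE)]
  if (length(miss))
    stop("stage '", stage, "' requires config fields: ",
         paste(miss, collapse = ", "))
  gone <- fields[!vapply(fields, function(f) file.exists(config[[f]]), TRUE)]
  if (length(gone))
    stop("stage '", stage, "' inputs not found: ",
         paste(unlist(config[gone]), collapse = ", "))
}

#' Run the gene-family evolution pipeline
#'
#' Executes the requested stages in order (classify, dup, date, expr,
#' promoters), validating that every requested stage has its inputs before
#' any work starts.  Returns all stage tables plus a summary with origin
#' percentages computed as `round(100 * count / family size, 1)`.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run.
#' @return list with elements per stage (`classification`, `tandem`,
#'   `blocks`, `origin`, `dates`, `expression`, `promoters`) and `summary`.
#' @export
run_pipeline <- function(config,
                         stages = c("classify", "dup", "date", "expr",
                                    "promoters")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  for (st in stages) {
    need <- switch(st,
      classify = c("proteins", "family"),
      dup = c("gff", "proteins", "family"),
      date = c("gff", "cds", "proteins", "family"),
      expr = "expression",
      promoters = c("promoters", "catalog"))
    require_inputs(config, st, need)
  }
  out <- list(config = config)

  read_family <- function() {
    fam <- readLines(config$family, warn = FALSE)
    fam[nzchar(fam)]
  }

  if ("classify" %in% stages) {
    prot <- read_fasta(config$proteins, "protein")
    fam <- read_family()
    refs <- if (!is.null(config$subgroup_refs))
      read.delim(config$subgroup_refs, stringsAsFactors = FALSE)
    else load_subgroup_refs()
    out$classification <- classify_family(prot[intersect(fam, names(prot))],
                                          refs = refs)
  }

  genes <- NULL
  blocks <- NULL
  if (any(c("dup", "date") %in% stages)) {
    genes <- parse_gff3(config$gff)
    prot <- read_fasta(config$proteins, "protein")
    fam <- read_family()
    out$gene_structure <- summarize_gene_structure(genes)
    out$tandem <- find_tandem(genes, fam, config$max_intervening)
    bm <- best_nonself_matches(prot)
    blocks <- find_segmental_all(fam, genes, bm,
                                 window_kb = config$window_kb,
                                 min_anchors = config$min_anchors)
    out$blocks <- blocks
    out$origin <- classify_origin(fam, out$tandem, blocks)
  }

  if ("date" %in% stages && length(blocks)) {
    cds <- read_fasta(config$cds, "dna")
    rows <- lapply(blocks, function(b) {
      ks <- vapply(seq_len(nrow(b$anchors)), function(i)
        tryCatch(align_pair_kaks(cds[[b$anchors$gene[i]]],
                                 cds[[b$anchors$match[i]]])$ks,
                 error = function(e) NA_real_), 0)
      bs <- block_ks(ks[!is.na(ks)], cutoff = config$ks_cutoff)
      data.frame(pair = paste(b$focal, "&", b$paralog),
                 n_anchors = b$n_anchors,
                 mean_ks = bs$mean_ks, sd_ks = bs$sd_ks,
                 n_retained = bs$n_retained,
                 time_mya = if (is.na(bs$mean_ks)) NA_real_
                            else date_duplication(bs$mean_ks, config$lambda,
                                                  rounded = TRUE),
                 stringsAsFactors = FALSE)
    })
    out$dates <- do.call(rbind, rows)
  } else if ("date" %in% stages) {
    out$dates <- data.frame(pair = character(0), n_anchors = integer(0),
                            mean_ks = numeric(0), sd_ks = numeric(0),
                            n_retained = integer(0), time_mya = numeric(0))
  }

  if ("expr" %in% stages) {
    x <- as.matrix(read.delim(config$expression, row.names = 1,
                              check.names = FALSE))
    out$expression <- list(z = zscore_rows(x),
                           breadth = classify_breadth(
                             x, config$expressed_cutoff, config$peak_z))
    cl <- tryCatch(suppressWarnings(cluster_expression(zscore_rows(x))),
                   error = function(e) NULL)
    out$expression$clustering <- cl
  }

  if ("promoters" %in% stages) {
    proms <- read_fasta(config$promoters, "dna")
    catalog <- load_cis_catalog(config$catalog)
    out$promoters <- scan_cis_elements(proms, catalog)
  }

  if (!is.null(out$origin)) {
    os <- origin_summary(out$origin)
    group_counts <- if (!is.null(out$classification))
      table(out$classification$group) else NULL
    out$summary <- list(family_size = nrow(out$origin),
                        group_counts = group_counts,
                        origin_counts = os$counts,
                        origin_percent = os$percent)
  }
  out
}
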