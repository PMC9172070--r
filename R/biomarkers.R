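#' Top-ranked LNE genes of one sample
#'
#' Ranks the sample's genes by the per-gene local score `dE * dSD` and keeps
#' the top `ceil(fraction * Q)`; ties at the cutoff are broken
#' lexicographically by gene symbol so the set is deterministic. The default
#' fraction is 0.05 (the top 5 percent).
#'
#' @param score a `sample_score` (see [score_sample()]).
#' @param fraction fraction of genes to keep, in `(0, 1]`.
#' @return object of class `lne_gene_set`: list with `sample_id`, `stage`,
#'   `genes` (character vector, score order) and `fraction`.
#' @export
lne_genes <- function(score, fraction = 0.05) {
  stopifnot(inherits(score, "sample_score"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1], got ", fraction)
  p <- score$profiles
  k <- ceiling(fraction * nrow(p))
  ord <- order(-p$score, p$gene)
  structure(list(sample_id = score$sample_id, stage = score$stage,
                 genes = p$gene[ord][seq_len(k)], fraction = fraction),
            class = "lne_gene_set")
}

#' Common LNE genes of critical-state samples (DNB extraction)
#'
#' The genes shared by the LNE gene sets of the samples in a given stage are
#' taken as the dynamic network biomarker (DNB) candidates of that stage.
#' `min_fraction = 1` (default) is a strict intersection; lower values keep
#' genes present in at least that fraction of the stage's sets.
#'
#' @param sets list of `lne_gene_set` objects.
#' @param samples_at stage label selecting the sets to intersect; `NULL`
#'   uses all sets.
#' @param min_fraction minimum fraction of sets a gene must appear in.
#' @return character vector of common genes (possibly empty, with a warning).
#' @export
common_lne_genes <- function(sets, samples_at = NULL, min_fraction = 1) {
  if (!is.null(samples_at)) {
    sets <- Filter(function(s) identical(s$stage, samples_at), sets)
    if (length(sets) == 0) stop("no LNE gene sets at stage ", samples_at)
  }
  if (length(sets) == 0) stop("no LNE gene sets supplied")
  counts <- table(unlist(lapply(sets, `[[`, "genes")))
  common <- sort(names(counts)[counts >= min_fraction * length(sets)])
  if (length(common) == 0)
    warning("common LNE gene set is empty across ", length(sets), " samples")
  common
}

#' Classify optimistic / pessimistic prognostic biomarkers
#'
#' For each candidate gene, case samples are split into those whose LNE gene
#' set contains the gene ("with") and the rest ("without"); a log-rank test
#' compares the two groups and the direction is read from the restricted mean
#' survival of the two Kaplan-Meier curves. A gene is an optimistic (O-LNE)
#' biomarker when the with-group survives significantly longer, pessimistic
#' (P-LNE) when significantly shorter, and `neither` otherwise. Genes whose
#' with- or without-group is smaller than `min_group` (in particular empty)
#' are `neither` with p reported as 1: the asymptotic log-rank test is
#' meaningless on one or two samples.
#'
#' @param sets list of `lne_gene_set` objects, one per case sample.
#' @param clinical data.frame with columns `sample_id`, `time`, `event`.
#' @param alpha significance level for the log-rank test (default 0.05).
#' @param candidates genes to classify; default is the union of all sets.
#' @param min_group smallest admissible group size (default 3).
#' @return data.frame with columns `gene`, `class` (`"O-LNE"`, `"P-LNE"`,
#'   `"neither"`), `with_n`, `without_n`, `logrank_stat`, `logrank_p`,
#'   `direction` (`"longer"`, `"shorter"`, `"none"`).
#' @export
classify_biomarkers <- function(sets, clinical, alpha = 0.05, candidates = NULL,
                                min_group = 3) {
  ids <- vapply(sets, `[[`, character(1), "sample_id")
  if (is.null(candidates))
    candidates <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  if (length(candidates) == 0) stop("no candidate genes")
  keep <- ids %in% clinical$sample_id
  sets <- sets[keep]; ids <- ids[keep]
  cl <- clinical[match(ids, clinical$sample_id), ]
  membership <- vapply(sets, function(s) candidates %in% s$genes,
                       logical(length(candidates)))
  membership <- matrix(membership, nrow = length(candidates))
  out <- lapply(seq_along(candidates), function(i) {
    w <- membership[i, ]
    if (sum(w) < min_group || sum(!w) < min_group)
      return(data.frame(gene = candidates[i], class = "neither",
                        with_n = sum(w), without_n = sum(!w),
                        logrank_stat = 0, logrank_p = 1, direction = "none",
                        stringsAsFactors = FALSE))
    lr <- suppressWarnings(
      logrank_test(cl$time[w], cl$event[w], cl$time[!w], cl$event[!w]))
    tau <- max(cl$time)
    rw <- km_rmst(km_curve(cl$time[w], cl$event[w]), tau)
    rwo <- km_rmst(km_curve(cl$time[!w], cl$event[!w]), tau)
    dir <- if (rw > rwo) "longer" else if (rw < rwo) "shorter" else "none"
    cls <- if (lr$p_value < alpha && dir == "longer") "O-LNE"
           else if (lr$p_value < alpha && dir == "shorter") "P-LNE"
           else "neither"
    data.frame(gene = candidates[i], class = cls, with_n = sum(w),
               without_n = sum(!w), logrank_stat = lr$statistic,
               logrank_p = lr$p_value, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Dark genes: differential entropy without differential expression
#'
#' A dark gene shows no case-vs-reference difference in expression level
#' (two-sided Wilcoxon rank-sum, Benjamini-Hochberg adjusted p >= `de_alpha`)
#' but a significant difference in its per-sample local LNE score `dE * dSD`
#' between case samples before the transition and those at/after it
#' (rank-sum, BH-adjusted p < `lne_alpha`). Such genes carry network-level
#' early-warning signal that expression-based tests miss.
#'
#' @param study an [expression_study] (>= 3 reference and >= 3 case samples).
#' @param scores list of `sample_score` objects for the case samples.
#' @param transition transition stage label.
#' @param stage_order clinical stage ordering.
#' @param de_alpha adjusted-p threshold below which a gene counts as
#'   differentially expressed (and is therefore excluded). Default 0.05.
#' @param lne_alpha adjusted-p threshold for the LNE-score difference.
#'   Default 0.05.
#' @return character vector of dark-gene symbols; the full per-gene test
#'   table is attached as attribute `"table"`.
#' @export
dark_genes <- function(study, scores, transition, stage_order,
                       de_alpha = 0.05, lne_alpha = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  is_ref <- study$samples$group == "reference"
  if (sum(is_ref) < 3 || sum(!is_ref) < 3)
    stop("need at least 3 reference and 3 case samples")
  genes <- scores[[1]]$profiles$gene
  expr <- study$expr[genes, , drop = FALSE]

  de_p <- vapply(genes, function(g) {
    suppressWarnings(stats::wilcox.test(expr[g, !is_ref], expr[g, is_ref],
                                        exact = FALSE)$p.value)
  }, numeric(1))

  stages <- vapply(scores, `[[`, character(1), "stage")
  at_or_after <- match(stages, stage_order) >= match(transition, stage_order)
  if (sum(at_or_after) == 0 || sum(!at_or_after) == 0)
    stop("need case samples both before and at/after the transition")
  smat <- vapply(scores, function(s) s$profiles$score, numeric(length(genes)))
  lne_p <- vapply(seq_along(genes), function(i) {
    suppressWarnings(stats::wilcox.test(smat[i, at_or_after], smat[i, !at_or_after],
                                        exact = FALSE)$p.value)
  }, numeric(1))

  de_adj <- stats::p.adjust(de_p, "BH")
  lne_adj <- stats::p.adjust(lne_p, "BH")
  de_adj[is.na(de_adj)] <- 1      # constant genes: no evidence of DE
  lne_adj[is.na(lne_adj)] <- 1
  dark <- genes[de_adj >= de_alpha & lne_adj < lne_alpha]
  structure(dark, table = data.frame(gene = genes, de_p = de_p, de_adj = de_adj,
                                     lne_p = lne_p, lne_adj = lne_adj,
                                     stringsAsFactors = FALSE))
}

#' Export a DNB subnetwork for Cytoscape
#'
#' Induces the template network on a DNB gene set and writes SIF and GraphML
#' files. Nodes carry the mean per-gene local score `dE * dSD` over the
#' supplied samples; edges carry the absolute Pearson correlation computed
#' from the given expression matrix (mirroring node/edge coloring by scaled
#' local LNE score and |PCC|).
#'
#' @param genes DNB gene symbols.
#' @param net the template [gene_network].
#' @param scores list of `sample_score` objects used for the node attribute
#'   (typically the critical-stage samples).
#' @param expr genes x samples matrix used for edge |PCC| (typically the
#'   reference cohort plus critical-stage samples).
#' @param prefix output path prefix; writes `<prefix>.sif` and
#'   `<prefix>.graphml`.
#' @return the induced [gene_network], invisibly.
#' @export
export_dnb_subnetwork <- function(genes, net, scores, expr, prefix) {
  sub <- restrict_to_genes(net, genes)
  smat <- vapply(scores, function(s) s$profiles$score,
                 numeric(nrow(scores[[1]]$profiles)))
  node_score <- rowMeans(matrix(smat, ncol = length(scores)))
  names(node_score) <- scores[[1]]$profiles$gene
  edge_pcc <- vapply(seq_len(nrow(sub$edges)), function(i) {
    abs(pcc(expr[sub$edges$from[i], ], expr[sub$edges$to[i], ]))
  }, numeric(1))
  export_sif(sub, paste0(prefix, ".sif"))
  export_graphml(sub, paste0(prefix, ".graphml"),
                 node_attr = node_score[sub$nodes], edge_attr = edge_pcc)
  invisible(sub)
}
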