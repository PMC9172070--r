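#' Expression studies
#'
#' Container pairing a genes x samples expression matrix with a sample
#' annotation table. Reference samples (`group == "reference"`) define the
#' baseline correlation structure; every other sample is a case sample with a
#' clinical stage label.
#'
#' @param expr numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns (colnames are sample IDs).
#' @param annotations data.frame with columns `sample_id`, `group`
#'   (`"reference"` or `"case"`) and `stage` (stage label; may be `NA` for
#'   reference samples).
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(expr, annotations) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  req <- c("sample_id", "group", "stage")
  if (!all(req %in% names(annotations)))
    stop("annotations must have columns: ", paste(req, collapse = ", "))
  annotations <- annotations[, req]
  missing <- setdiff(colnames(expr), annotations$sample_id)
  if (length(missing) > 0)
    stop("samples without annotation: ", paste(utils::head(missing, 5), collapse = ", "))
  annotations <- annotations[match(colnames(expr), annotations$sample_id), ]
  if (anyNA(expr)) {
    bad <- rownames(expr)[apply(is.na(expr), 1, any)]
    stop("genes with missing expression values are not supported (",
         length(bad), " affected, e.g. ", paste(utils::head(bad, 3), collapse = ", "),
         "); remove or impute upstream")
  }
  structure(list(expr = expr, samples = annotations), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  is_ref <- x$samples$group == "reference"
  cat(sprintf("expression_study: %d genes, %d reference + %d case samples\n",
              nrow(x$expr), sum(is_ref), sum(!is_ref)))
  invisible(x)
}

#' @rdname expression_study
#' @param study an `expression_study`.
#' @return `reference_cohort()`: the reference expression sub-matrix
#'   (genes x n).
#' @export
reference_cohort <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  ref <- study$expr[, study$samples$group == "reference", drop = FALSE]
  if (ncol(ref) < 3)
    stop("need at least 3 reference samples for Pearson correlation, got ", ncol(ref))
  ref
}

#' @rdname expression_study
#' @return `case_samples()`: data.frame of case `sample_id` and `stage`.
#' @export
case_samples <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  cs <- study$samples[study$samples$group != "reference", c("sample_id", "stage")]
  rownames(cs) <- NULL
  cs
}

#' Pearson correlation with a zero-variance convention
#'
#' Pearson correlation between two vectors, defined as 0 when either vector
#' is constant (no evidence of association) instead of `NA`. Used everywhere
#' a local correlation weight is formed.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or 0 for zero-variance input.
#' @export
pcc <- function(x, y) {
  if (length(x) < 3) stop("Pearson correlation needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Normalized absolute correlation weights of a local network
#'
#' For a center gene g with neighbors g_1..g_M, the weight of neighbor i is
#' `|PCC(g_i, g)| / sum_j |PCC(g_j, g)|`, the normalized absolute Pearson
#' correlation computed across the columns of `expr`. If every correlation is
#' zero (e.g. all genes constant) the uniform vector `1/M` is returned, so the
#' local entropy is maximal rather than undefined.
#'
#' @param center center gene symbol.
#' @param hood a `local_neighborhood` from [neighborhood()].
#' @param expr genes x m numeric matrix with m >= 3 columns containing the
#'   center and all neighbors.
#' @return numeric weight vector of length `hood$M`, named by neighbor,
#'   summing to 1.
#' @export
correlation_weights <- function(center, hood, expr) {
  stopifnot(inherits(hood, "local_neighborhood"))
  if (ncol(expr) < 3) stop("need at least 3 samples to compute correlations")
  missing <- setdiff(c(center, hood$neighbors), rownames(expr))
  if (length(missing) > 0)
    stop("genes absent from expression matrix: ", paste(missing, collapse = ", "))
  w <- vapply(hood$neighbors, function(nb) abs(pcc(expr[nb, ], expr[center, ])),
              numeric(1))
  s <- sum(w)
  if (s > 0) w / s else stats::setNames(rep(1 / hood$M, hood$M), hood$neighbors)
}

#' Local network entropy of a weight vector
#'
#' Shannon-type entropy of the local correlation weights, scaled by the
#' neighborhood size: `-(1/M) * sum_i p_i * ln p_i`, with `0 * ln 0 := 0`.
#' Natural logarithm throughout; any other base rescales all scores by a
#' constant and leaves rankings and the called transition unchanged. The
#' value lies in `[0, ln(M)/M]`, with the maximum at uniform weights.
#'
#' @param p nonnegative weight vector summing to 1 (or identically 0, which
#'   yields entropy 0).
#' @param M neighborhood size; must equal `length(p)`.
#' @return local entropy, a nonnegative scalar.
#' @export
local_entropy <- function(p, M = length(p)) {
  if (length(p) != M) stop("length(p) must equal M")
  if (any(p < 0)) stop("weights must be nonnegative")
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / M
}

## Internal vectorized engine -------------------------------------------------
##
## Scoring touches every gene for every case sample, so the per-gene formulas
## are evaluated edge-wise over the whole network at once:
##   * rows of the expression matrix are standardized, so the Pearson
##     correlation of an edge is the cross-product of its standardized rows
##     divided by (m - 1); constant rows standardize to zero, giving PCC = 0;
##   * each edge contributes |PCC| to both endpoints; per-gene normalization
##     and entropy are computed by grouped sums (rowsum).

.standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  z <- (x - mu) / sdv
  z[sdv == 0, ] <- 0
  z
}

# Per-gene local entropies for all network genes given an expression matrix.
# Returns a numeric vector ordered like `net$nodes`.
.entropies_all <- function(net, expr) {
  z <- .standardize_rows(expr[net$nodes, , drop = FALSE])
  m <- ncol(expr)
  ia <- match(net$edges$from, net$nodes)
  ib <- match(net$edges$to, net$nodes)
  r <- rowSums(z[ia, , drop = FALSE] * z[ib, , drop = FALSE]) / (m - 1)
  w <- abs(r)
  gidx <- c(ia, ib)                   # each edge contributes to both endpoints
  wex <- c(w, w)
  gf <- factor(gidx, levels = seq_along(net$nodes))
  M <- as.vector(table(gf))
  S <- as.vector(rowsum(wex, gf))
  p <- wex / S[gidx]
  p[S[gidx] == 0] <- 1 / M[gidx][S[gidx] == 0]    # all-zero weights -> uniform
  term <- ifelse(p > 0, p * log(p), 0)
  -as.vector(rowsum(term, gf)) / M
}

.row_sds <- function(x) {
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
}

#' Score one case sample against a reference cohort
#'
#' Computes, for every network gene k, the local network entropy from the n
#' reference samples and from the n+1 samples formed by mixing the case
#' sample into the cohort; their absolute difference `dE`; the absolute
#' change `dSD` in the gene's (sample, n-1 denominator) standard deviation;
#' and the per-gene score `dE * dSD`. The global LNE score of the sample is
#' the mean of `dE * dSD` over all Q network genes.
#'
#' @param case named numeric vector of the case sample's expression, covering
#'   every network gene.
#' @param ref genes x n reference expression matrix, n >= 3.
#' @param net a [gene_network], already restricted to genes present in both
#'   `case` and `ref` (see [restrict_to_genes()]).
#' @param sample_id,stage labels carried through to the result.
#' @return an object of class `sample_score`: list with `sample_id`, `stage`,
#'   `global_dE`, `Q` and `profiles`, a data.frame with one row per network
#'   gene and columns `gene`, `E_ref`, `E_mixed`, `dE`, `dSD`, `score`.
#' @export
score_sample <- function(case, ref, net, sample_id = "case", stage = NA_character_) {
  stopifnot(inherits(net, "gene_network"))
  if (ncol(ref) < 3)
    stop("reference cohort must have n >= 3 samples, got ", ncol(ref))
  missing <- setdiff(net$nodes, intersect(names(case), rownames(ref)))
  if (length(missing) > 0)
    stop("case/reference missing network genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ref <- ref[net$nodes, , drop = FALSE]
  mixed <- cbind(ref, case[net$nodes])

  E_ref <- .entropies_all(net, ref)
  E_mixed <- .entropies_all(net, mixed)
  dE <- abs(E_mixed - E_ref)
  dSD <- abs(.row_sds(ref) - .row_sds(mixed))
  score <- dE * dSD
  structure(
    list(sample_id = sample_id, stage = stage,
         global_dE = mean(score), Q = length(net$nodes),
         profiles = data.frame(gene = net$nodes, E_ref = E_ref,
                               E_mixed = E_mixed, dE = dE, dSD = unname(dSD),
                               score = unname(score), stringsAsFactors = FALSE)),
    class = "sample_score")
}

#' @export
print.sample_score <- function(x, ...) {
  cat(sprintf("sample_score %s (stage %s): global LNE = %.6g over Q = %d genes\n",
              x$sample_id, x$stage, x$global_dE, x$Q))
  invisible(x)
}

#' Score every case sample of a study
#'
#' Each case sample is mixed into the reference cohort alone; the cohort is
#' untouched between samples. The network is restricted to the study's genes
#' first (isolated nodes re-pruned), so Q is the number of genes with a
#' defined local entropy.
#'
#' @param study an [expression_study].
#' @param net a [gene_network].
#' @param log_transform if `TRUE`, apply `log2(x + 1)` to the expression
#'   matrix before any correlation or standard deviation is computed
#'   (useful for raw RNA-seq quantifications). Default off.
#' @return list of [score_sample()] results, one per case sample, named by
#'   sample ID.
#' @export
score_cohort <- function(study, net, log_transform = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  cs <- case_samples(study)
  if (nrow(cs) == 0) stop("study has no case samples")
  expr <- study$expr
  if (log_transform) {
    if (any(expr < 0)) stop("log_transform requires nonnegative expression values")
    expr <- log2(expr + 1)
  }
  net <- restrict_to_genes(net, rownames(expr))
  ref <- expr[, study$samples$group == "reference", drop = FALSE]
  if (ncol(ref) < 3)
    stop("need at least 3 reference samples, got ", ncol(ref))
  out <- lapply(seq_len(nrow(cs)), function(i) {
    score_sample(expr[, cs$sample_id[i]], ref, net,
                 sample_id = cs$sample_id[i], stage = cs$stage[i])
  })
  names(out) <- cs$sample_id
  out
}

#' Tabulate cohort scores
#'
#' @param scores list of `sample_score` objects.
#' @return data.frame with columns `sample_id`, `stage`, `global_dE`.
#' @export
score_table <- function(scores) {
  data.frame(sample_id = vapply(scores, `[[`, character(1), "sample_id"),
             stage = vapply(scores, `[[`, character(1), "stage"),
             global_dE = vapply(scores, `[[`, numeric(1), "global_dE"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample profile table with ranks
#'
#' @param score a `sample_score`.
#' @return the profile data.frame augmented with `rank` (1 = highest
#'   `dE * dSD`; ties broken lexicographically by gene).
#' @export
profile_table <- function(score) {
  stopifnot(inherits(score, "sample_score"))
  p <- score$profiles
  ord <- order(-p$score, p$gene)
  p$rank <- integer(nrow(p))
  p$rank[ord] <- seq_len(nrow(p))
  p
}
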