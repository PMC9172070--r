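# Shared fixture builders; everything is generated in code.

# Write a small edge-list file and return its path.
edge_file <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".txt.gz" else ".txt")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

# Network from a plain character edge matrix.
net_from <- function(...) {
  gene_network(matrix(c(...), ncol = 2, byrow = TRUE))
}

# Random toy study on a random connected-ish network; for oracle comparisons.
random_toy <- function(seed, max_genes = 10, max_samples = 8) {
  set.seed(seed)
  q <- sample(3:max_genes, 1)
  genes <- sprintf("G%02d", seq_len(q))
  # random tree plus extra edges guarantees degree >= 1 everywhere
  edges <- cbind(genes[-1], genes[sapply(2:q, function(i) sample(i - 1, 1))])
  extra <- q %/% 2
  if (extra > 0) {
    a <- sample(genes, extra, replace = TRUE)
    b <- sample(genes, extra, replace = TRUE)
    keep <- a != b
    edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  net <- gene_network(edges)
  n_ref <- sample(3:(max_samples - 1), 1)
  ref <- matrix(stats::rnorm(q * n_ref), nrow = q,
                dimnames = list(genes, sprintf("R%d", seq_len(n_ref))))
  case <- stats::setNames(stats::rnorm(q), genes)
  list(net = net, ref = ref, case = case)
}

# Minimal sample_score stub for tipping/biomarker unit tests.
stub_score <- function(sample_id, stage, global_dE = 0,
                       genes = NULL, scores = NULL) {
  profiles <- if (is.null(genes)) {
    data.frame(gene = character(0), E_ref = numeric(0), E_mixed = numeric(0),
               dE = numeric(0), dSD = numeric(0), score = numeric(0))
  } else {
    data.frame(gene = genes, E_ref = 0, E_mixed = 0, dE = 0, dSD = 0,
               score = scores, stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, stage = stage, global_dE = global_dE,
                 Q = length(genes), profiles = profiles),
            class = "sample_score")
}

# Small, fast simulator configuration for pipeline round-trip tests.
small_cfg <- function(seed = 1, ...) {
  args <- list(n_genes = 30, module_size = 5, n_boundary = 5, bg_degree = 6,
               stages = c("I", "II", "III"), critical_stage = "II",
               n_ref = 10, n_per_stage = 5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
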