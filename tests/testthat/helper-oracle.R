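# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops, stats::cor / stats::sd, no vectorized edge
# arithmetic.

# Pearson correlation that returns 0 for zero-variance input.
oracle_pcc <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Local entropy of one gene from an expression matrix and an edge table.
oracle_local_entropy <- function(gene, expr, edges) {
  nbs <- sort(unique(c(edges$to[edges$from == gene],
                       edges$from[edges$to == gene])))
  M <- length(nbs)
  w <- numeric(M)
  for (i in seq_len(M)) w[i] <- abs(oracle_pcc(expr[nbs[i], ], expr[gene, ]))
  s <- sum(w)
  p <- if (s > 0) w / s else rep(1 / M, M)
  e <- 0
  for (pi in p) if (pi > 0) e <- e - pi * log(pi)
  e / M
}

# Straight-line implementation of the whole per-sample score.
oracle_score_sample <- function(case, ref, edges) {
  genes <- sort(unique(c(edges$from, edges$to)))
  mixed <- cbind(ref, case[rownames(ref)])
  per <- data.frame(gene = genes, E_ref = NA_real_, E_mixed = NA_real_,
                    dE = NA_real_, dSD = NA_real_, score = NA_real_)
  for (i in seq_along(genes)) {
    g <- genes[i]
    en <- oracle_local_entropy(g, ref, edges)
    en1 <- oracle_local_entropy(g, mixed, edges)
    dsd <- abs(stats::sd(ref[g, ]) - stats::sd(mixed[g, ]))
    per[i, 2:6] <- c(en, en1, abs(en1 - en), dsd, abs(en1 - en) * dsd)
  }
  list(global_dE = mean(per$score), profiles = per)
}

# Log-rank via an explicit observed-minus-expected risk-set table.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    n <- sum(risk); n1 <- sum(risk & in_a)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_a)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  if (v == 0) return(list(statistic = 0, p = 1))
  stat <- (o - e)^2 / v
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}
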