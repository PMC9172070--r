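test_that("local_entropy matches closed forms and the independent oracle", {
  expect_identical(local_entropy(1), 0)
  expect_equal(local_entropy(c(0.5, 0.5)), log(2) / 2)
  # -(1/2)(0.75 ln 0.75 + 0.25 ln 0.25), evaluated independently
  expect_equal(local_entropy(c(0.75, 0.25)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / 2,
               tolerance = 1e-15)
  expect_equal(local_entropy(c(0.75, 0.25)), 0.2811676, tolerance = 1e-6)
  expect_identical(local_entropy(c(0, 1)), 0)
  expect_error(local_entropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(local_entropy(c(0.5, 0.5), M = 3), "length")
})

test_that("entropy bounds hold with equality only at uniform weights", {
  set.seed(42)
  for (i in 1:200) {
    M <- sample(1:12, 1)
    w <- stats::rexp(M)
    p <- w / sum(w)
    e <- local_entropy(p, M)
    expect_gte(e, 0)
    expect_lte(e, log(M) / M + 1e-12)
  }
  for (M in c(1, 2, 5, 20))
    expect_equal(local_entropy(rep(1 / M, M), M), if (M == 1) 0 else log(M) / M)
})

test_that("correlation_weights normalizes |PCC| with degenerate conventions", {
  net <- net_from("C", "N1", "C", "N2")
  hood <- neighborhood(net, "C")
  set.seed(1)
  expr <- matrix(rnorm(15), nrow = 3, dimnames = list(c("C", "N1", "N2"), NULL))
  p <- correlation_weights("C", hood, expr)
  w <- c(abs(oracle_pcc(expr["N1", ], expr["C", ])),
         abs(oracle_pcc(expr["N2", ], expr["C", ])))
  expect_equal(unname(p), w / sum(w), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # single neighbor -> p = 1 regardless of the data
  star <- net_from("C", "N1")
  expect_equal(unname(correlation_weights("C", neighborhood(star, "C"), expr)), 1)

  # constant neighbor: PCC defined as 0, all weight on the informative one
  expr2 <- expr
  expr2["N1", ] <- 7
  expect_equal(unname(correlation_weights("C", hood, expr2)), c(0, 1))

  # all correlations zero -> uniform fallback
  expr3 <- expr
  expr3["C", ] <- 2
  expect_equal(unname(correlation_weights("C", hood, expr3)), c(0.5, 0.5))

  expect_error(correlation_weights("C", hood, expr[, 1:2]), "3 samples")
  expect_error(correlation_weights("C", hood, expr[c("C", "N1"), ]), "N2")
})

test_that("score_sample agrees with the brute-force oracle on random toys", {
  for (seed in 1:12) {
    toy <- random_toy(seed)
    got <- score_sample(toy$case, toy$ref, toy$net)
    want <- oracle_score_sample(toy$case, toy$ref, toy$net$edges)
    expect_equal(got$global_dE, want$global_dE, tolerance = 1e-12)
    expect_equal(got$profiles$E_ref, want$profiles$E_ref, tolerance = 1e-12)
    expect_equal(got$profiles$dSD, want$profiles$dSD, tolerance = 1e-12)
    expect_equal(got$Q, length(toy$net$nodes))
    # non-negativity
    expect_true(all(got$profiles$dE >= 0) && all(got$profiles$dSD >= 0))
    expect_gte(got$global_dE, 0)
  }
})

test_that("all-constant study gives global_dE exactly zero", {
  net <- net_from("A", "B", "B", "C")
  ref <- matrix(5, nrow = 3, ncol = 4, dimnames = list(c("A", "B", "C"), NULL))
  case <- c(A = 5, B = 5, C = 5)
  s <- score_sample(case, ref, net)
  expect_identical(s$global_dE, 0)
  expect_identical(s$profiles$dE, rep(0, 3))
  # degenerate weights fall back to uniform => entropies at the maximum
  expect_equal(s$profiles$E_ref,
               log(vapply(s$profiles$gene, function(g) neighborhood(net, g)$M,
                          numeric(1))) /
                 vapply(s$profiles$gene, function(g) neighborhood(net, g)$M,
                        numeric(1)),
               ignore_attr = TRUE)
})

test_that("positive rescaling leaves p and dE unchanged, scales dSD linearly", {
  toy <- random_toy(99)
  s1 <- score_sample(toy$case, toy$ref, toy$net)
  c_scale <- 3.7
  s2 <- score_sample(toy$case * c_scale, toy$ref * c_scale, toy$net)
  expect_equal(s2$profiles$dE, s1$profiles$dE, tolerance = 1e-12)
  expect_equal(s2$profiles$dSD, c_scale * s1$profiles$dSD, tolerance = 1e-12)
  expect_equal(s2$global_dE, c_scale * s1$global_dE, tolerance = 1e-12)
})

test_that("score_cohort scores each case against the untouched reference", {
  toy <- random_toy(7)
  genes <- rownames(toy$ref)
  # two identical case samples -> identical scores; reference untouched
  expr <- cbind(toy$ref, S1 = toy$case[genes], S2 = toy$case[genes])
  ann <- data.frame(
    sample_id = colnames(expr),
    group = c(rep("reference", ncol(toy$ref)), "case", "case"),
    stage = c(rep(NA, ncol(toy$ref)), "I", "II"))
  study <- expression_study(expr, ann)
  scores <- score_cohort(study, toy$net)
  expect_length(scores, 2)
  expect_equal(scores$S1$global_dE, scores$S2$global_dE)
  expect_equal(scores$S1$profiles, scores$S2$profiles)
  expect_equal(scores$S1$global_dE,
               score_sample(toy$case, toy$ref, toy$net)$global_dE)
  expect_equal(score_table(scores)$stage, c("I", "II"))

  ann_ref_only <- ann
  ann_ref_only$group <- "reference"
  expect_error(score_cohort(expression_study(expr, ann_ref_only), toy$net),
               "no case samples")
})

test_that("profile ranks order by dE*dSD with lexicographic ties", {
  s <- stub_score("s", "I", genes = c("B", "A", "C"), scores = c(2, 5, 2))
  tab <- profile_table(s)
  expect_equal(tab$rank[match(c("A", "B", "C"), tab$gene)], c(1L, 2L, 3L))
})

test_that("expression_study validates inputs", {
  expr <- matrix(1:6, nrow = 2,
                 dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  ann <- data.frame(sample_id = c("s1", "s2", "s3"),
                    group = c("reference", "reference", "case"),
                    stage = c(NA, NA, "I"))
  st <- expression_study(expr, ann)
  expect_equal(case_samples(st)$sample_id, "s3")
  expect_error(reference_cohort(st), "at least 3")

  expr_na <- expr; expr_na[1, 1] <- NA
  expect_error(expression_study(expr_na, ann), "missing expression")
  expect_error(expression_study(expr, ann[1:2, ]), "without annotation")
})
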