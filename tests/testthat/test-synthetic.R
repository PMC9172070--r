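test_that("sim_config validates the DNB orderings and PSD realizability", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(rho_in_base = 0.7, rho_in_crit = 0.2), "rho_in_crit")
  expect_error(sim_config(rho_out_base = 0.05, rho_out_crit = 0.3), "rho_out_crit")
  expect_error(sim_config(sd_base = 2, sd_crit = 1), "sd_crit")
  expect_error(sim_config(module_size = 100), "module_size")
  expect_error(sim_config(critical_stage = "X"), "critical_stage")
  # rho_out^2 > rho_in is not realizable as a PSD correlation
  expect_error(sim_config(rho_in_base = 0.04, rho_out_base = 0.3),
               "positive semi-definite.*rho_out")
  # null configuration allowed with a warning
  expect_warning(sim_config(rho_in_crit = 0.2, rho_out_crit = 0.3, sd_crit = 1),
                 "null configuration")
})

test_that("simulate_study is deterministic and labeled correctly", {
  cfg <- small_cfg(seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$study$expr, b$study$expr)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$study$expr, simulate_study(small_cfg(seed = 43))$study$expr))

  ann <- a$study$samples
  expect_equal(sum(ann$group == "reference"), cfg$n_ref)
  expect_equal(sum(ann$group == "case"), cfg$n_per_stage * length(cfg$stages))
  expect_setequal(unique(ann$stage[ann$group == "case"]), cfg$stages)
  expect_equal(nrow(a$study$expr), cfg$n_genes)
  expect_setequal(a$truth$module_genes, sprintf("MOD%02d", 1:5))
})

test_that("generator moments converge to the configured DNB conditions", {
  cfg <- sim_config(n_per_stage = 500, n_ref = 500, seed = 11)
  sim <- simulate_study(cfg)
  expr <- sim$study$expr
  ann <- sim$study$samples
  mod <- sim$truth$module_genes
  bnd <- sim$truth$boundary_genes
  cols_for <- function(stage) ann$sample_id[ann$group == "case" &
                                            !is.na(ann$stage) & ann$stage == stage]
  mean_offdiag <- function(m) mean(m[upper.tri(m)])

  crit <- expr[, cols_for(cfg$critical_stage)]
  base <- expr[, cols_for(cfg$stages[1])]
  rin_crit <- mean_offdiag(stats::cor(t(crit[mod, ])))
  rin_base <- mean_offdiag(stats::cor(t(base[mod, ])))
  expect_gt(rin_crit - rin_base,
            (cfg$rho_in_crit - cfg$rho_in_base) / 2)
  expect_equal(rin_crit, cfg$rho_in_crit, tolerance = 0.1)

  rout_crit <- mean(stats::cor(t(crit[mod, ]), t(crit[bnd, ])))
  rout_base <- mean(stats::cor(t(base[mod, ]), t(base[bnd, ])))
  expect_lt(rout_crit, rout_base)
  expect_equal(rout_base, cfg$rho_out_base, tolerance = 0.1)

  sd_crit <- mean(apply(crit[mod, ], 1, stats::sd))
  sd_base <- mean(apply(base[mod, ], 1, stats::sd))
  expect_equal(sd_crit, cfg$sd_crit, tolerance = 0.15)
  expect_equal(sd_base, cfg$sd_base, tolerance = 0.15)

  # peaked trajectory: post-critical stage returns to baseline
  post <- expr[, cols_for("IV")]
  expect_equal(mean(apply(post[mod, ], 1, stats::sd)), cfg$sd_base,
               tolerance = 0.15)
})

test_that("null configuration yields a flat stage curve (ANOVA-style)", {
  flat <- 0
  for (seed in 1:5) {
    cfg <- suppressWarnings(
      small_cfg(seed = seed, rho_in_crit = 0.2, rho_out_crit = 0.3,
                sd_crit = 1, n_per_stage = 8))
    sim <- simulate_study(cfg)
    scores <- score_cohort(sim$study, simulate_network(cfg))
    tab <- score_table(scores)
    p <- stats::anova(stats::lm(global_dE ~ stage, tab))[["Pr(>F)"]][1]
    if (p > 0.05) flat <- flat + 1
  }
  expect_gte(flat, 3)
})

test_that("simulate_network wires a connected module and no isolated nodes", {
  cfg <- small_cfg(seed = 13)
  net <- simulate_network(cfg)
  expect_identical(net, simulate_network(cfg))     # deterministic
  expect_length(net$nodes, cfg$n_genes)
  degs <- lengths(net$adj)
  expect_true(all(degs >= 1))
  sub <- restrict_to_genes(net, sprintf("MOD%02d", 1:5))
  g <- igraph::graph_from_data_frame(sub$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("simulate_survival follows the configured hazard model", {
  cfg <- small_cfg(seed = 21)
  sim <- simulate_study(cfg)
  samples <- case_samples(sim$study)
  clin <- simulate_survival(sim$truth, samples, cfg)
  expect_identical(clin, simulate_survival(sim$truth, samples, cfg))
  expect_setequal(clin$sample_id, samples$sample_id)
  expect_true(all(clin$time > 0))

  # censoring_rate 1 -> every record censored
  cfg_cens <- small_cfg(seed = 21, censoring_rate = 1)
  clin_c <- simulate_survival(sim$truth, samples, cfg_cens)
  expect_true(all(clin_c$event == 0))
  expect_warning(
    res <- before_after_survival(
      lapply(seq_len(nrow(samples)), function(i)
        stub_score(samples$sample_id[i], samples$stage[i])),
      cfg$critical_stage, cfg$stages, clin_c),
    "no events")
  expect_equal(res$p_value, 1)

  # hazard_ratio 1 -> groups exchangeable, log-rank near-nominal
  cfg_null <- small_cfg(seed = 22, survival_hazard_ratio = 1,
                        censoring_rate = 0)
  sim_n <- simulate_study(cfg_null)
  clin_n <- simulate_survival(sim_n$truth, case_samples(sim_n$study), cfg_null)
  at_after <- match(case_samples(sim_n$study)$stage, cfg_null$stages) >=
    match(cfg_null$critical_stage, cfg_null$stages)
  lr <- logrank_test(clin_n$time[!at_after], clin_n$event[!at_after],
                     clin_n$time[at_after], clin_n$event[at_after])
  expect_gt(lr$p_value, 0.001)

  # hazard_ratio 4 with n = 40 per group separates clearly
  cfg_hr <- sim_config(seed = 23, n_per_stage = 40, stages = c("I", "II"),
                       critical_stage = "II", censoring_rate = 0)
  sim_hr <- simulate_study(cfg_hr)
  clin_hr <- simulate_survival(sim_hr$truth, case_samples(sim_hr$study), cfg_hr)
  st <- case_samples(sim_hr$study)$stage
  lr_hr <- logrank_test(clin_hr$time[st == "I"], clin_hr$event[st == "I"],
                        clin_hr$time[st == "II"], clin_hr$event[st == "II"])
  expect_lt(lr_hr$p_value, 0.05)
})

test_that("write_synthetic_study round-trips through the file readers", {
  cfg <- small_cfg(seed = 31)
  dir <- file.path(tempdir(), "synth_rt")
  paths <- write_synthetic_study(cfg, dir)
  objs <- attr(paths, "objects")

  expr <- read_expression(paths$expression)
  expect_equal(expr, objs$sim$study$expr)
  ann <- read_annotations(paths$annotations)
  expect_equal(ann, objs$sim$study$samples, ignore_attr = TRUE)
  clin <- read_clinical(paths$clinical)
  expect_equal(clin$time, objs$clinical$time)
  net <- load_edge_list(paths$network, threshold = 0.8)
  expect_equal(net$edges, objs$network$edges)
  unlink(dir, recursive = TRUE)
})
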