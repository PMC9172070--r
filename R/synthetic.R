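#' Configuration for the synthetic tipping-point generator
#'
#' The generator plants a dynamic-network-biomarker (DNB) module inside an
#' otherwise unstructured gene panel, following the three hallmarks of a
#' system approaching a critical transition: as the critical stage is reached,
#' (1) the correlation between module members rises sharply, (2) the
#' correlation between the module and outside genes falls, and (3) the
#' standard deviation of module genes rises drastically. Samples are drawn
#' from a per-stage multivariate normal realized through a single-factor
#' model with an exchangeable intra-module block, which is positive
#' semi-definite by construction; realizability requires
#' `rho_out^2 <= rho_in` at both baseline and critical settings, and the
#' constructor rejects parameter combinations that violate it.
#'
#' Two background genes are designated prognostic biomarkers: per case
#' sample, independent Bernoulli(`biomarker_prob`) indicators decide whether
#' the sample aberrantly expresses the optimistic and/or the pessimistic
#' gene (mean shift `biomarker_shift` in SD units); the survival simulator
#' ties hazards to these indicators so that membership of the gene in a
#' sample's LNE gene set stratifies survival.
#'
#' @param n_genes total number of genes (default 100).
#' @param module_size planted DNB module size (default 10).
#' @param stages ordered clinical stage labels (default I-IV).
#' @param critical_stage stage at which the module signal peaks
#'   (default "III").
#' @param n_ref reference cohort size (default 50, a typical tumor-adjacent
#'   cohort).
#' @param n_per_stage case samples per stage (default 20).
#' @param rho_in_base,rho_in_crit intra-module correlation at baseline /
#'   critical stage (defaults 0.2 / 0.7).
#' @param rho_out_base,rho_out_crit module-to-boundary correlation at
#'   baseline / critical stage (defaults 0.3 / 0.05).
#' @param sd_base,sd_crit module gene standard deviation at baseline /
#'   critical stage (defaults 1 / 2).
#' @param n_boundary number of background genes correlated with the module
#'   (default 10).
#' @param bg_degree target mean degree of the background graph (default 12,
#'   typical of STRING subnetworks at 0.8 confidence; sparser graphs make
#'   local entropies of background genes much noisier).
#' @param trajectory `"peaked"` (post-critical stages return to baseline,
#'   the characteristic rise-then-fall curve) or `"plateau"` (critical
#'   parameters persist).
#' @param survival_hazard_ratio hazard multiplier for at-risk samples
#'   (default 4).
#' @param median_survival baseline median survival time, arbitrary units
#'   (default 24).
#' @param censoring_rate probability that a record is censored (default 0.2).
#' @param biomarker_prob per-sample probability of carrying each planted
#'   prognostic biomarker (default 0.5).
#' @param biomarker_shift aberrant-expression shift of a carried biomarker,
#'   in SD units (default 3).
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 100, module_size = 10,
                       stages = c("I", "II", "III", "IV"),
                       critical_stage = "III",
                       n_ref = 50, n_per_stage = 20,
                       rho_in_base = 0.2, rho_in_crit = 0.7,
                       rho_out_base = 0.3, rho_out_crit = 0.05,
                       sd_base = 1, sd_crit = 2,
                       n_boundary = 10, bg_degree = 12,
                       trajectory = c("peaked", "plateau"),
                       survival_hazard_ratio = 4,
                       median_survival = 24,
                       censoring_rate = 0.2,
                       biomarker_prob = 0.5,
                       biomarker_shift = 3,
                       seed = 1L) {
  trajectory <- match.arg(trajectory)
  cfg <- list(n_genes = n_genes, module_size = module_size, stages = stages,
              critical_stage = critical_stage, n_ref = n_ref,
              n_per_stage = n_per_stage, rho_in_base = rho_in_base,
              rho_in_crit = rho_in_crit, rho_out_base = rho_out_base,
              rho_out_crit = rho_out_crit, sd_base = sd_base,
              sd_crit = sd_crit, n_boundary = n_boundary,
              bg_degree = bg_degree,
              trajectory = trajectory,
              survival_hazard_ratio = survival_hazard_ratio,
              median_survival = median_survival,
              censoring_rate = censoring_rate,
              biomarker_prob = biomarker_prob,
              biomarker_shift = biomarker_shift, seed = as.integer(seed))
  if (module_size >= n_genes) stop("module_size must be < n_genes")
  if (module_size < 2) stop("module_size must be >= 2")
  if (!critical_stage %in% stages) stop("critical_stage must be one of stages")
  if (rho_in_crit < rho_in_base) stop("rho_in_crit must be >= rho_in_base")
  if (rho_out_crit > rho_out_base) stop("rho_out_crit must be <= rho_out_base")
  if (sd_crit < sd_base) stop("sd_crit must be >= sd_base")
  if (rho_in_crit == rho_in_base && rho_out_crit == rho_out_base &&
      sd_crit == sd_base)
    warning("null configuration: no signal planted at the critical stage")
  if (any(c(rho_in_base, rho_in_crit) < 0) || any(c(rho_in_base, rho_in_crit) >= 1))
    stop("rho_in must be in [0, 1)")
  if (n_boundary + module_size + 2 > n_genes)
    stop("n_genes too small for module + boundary + biomarker genes")
  for (lbl in c("base", "crit")) {
    ri <- cfg[[paste0("rho_in_", lbl)]]; ro <- cfg[[paste0("rho_out_", lbl)]]
    if (ro^2 > ri)
      stop(sprintf(
        "covariance not positive semi-definite at %s stage: rho_out^2 = %.3g > rho_in = %.3g",
        lbl, ro^2, ri))
  }
  if (survival_hazard_ratio <= 0) stop("survival_hazard_ratio must be positive")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

.sim_gene_names <- function(cfg) {
  mod <- sprintf("MOD%02d", seq_len(cfg$module_size))
  bnd <- sprintf("BND%02d", seq_len(cfg$n_boundary))
  n_bg <- cfg$n_genes - cfg$module_size - cfg$n_boundary - 2
  bg <- if (n_bg > 0) sprintf("BG%03d", seq_len(n_bg)) else character(0)
  list(module = mod, boundary = bnd, opt = "OPT1", pess = "PES1",
       background = bg,
       all = c(mod, bnd, "OPT1", "PES1", bg))
}

# Stage parameters under the configured trajectory.
.stage_params <- function(cfg, stage) {
  i <- match(stage, cfg$stages)
  ic <- match(cfg$critical_stage, cfg$stages)
  hot <- i == ic || (i > ic && cfg$trajectory == "plateau")
  if (hot)
    list(rho_in = cfg$rho_in_crit, rho_out = cfg$rho_out_crit, sd = cfg$sd_crit)
  else
    list(rho_in = cfg$rho_in_base, rho_out = cfg$rho_out_base, sd = cfg$sd_base)
}

# Draw n samples (columns) under the factor model at the given parameters.
# opt/pess are logical vectors of per-sample biomarker indicators.
.sim_draw <- function(cfg, nm, n, par, opt, pess) {
  p <- cfg$n_genes
  x <- matrix(stats::rnorm(p * n), nrow = p,
              dimnames = list(nm$all, NULL))
  f <- stats::rnorm(n)                               # shared module factor
  im <- match(nm$module, nm$all)
  ib <- match(nm$boundary, nm$all)
  lam_m <- sqrt(par$rho_in)
  lam_b <- if (par$rho_in > 0) par$rho_out / sqrt(par$rho_in) else 0
  x[im, ] <- par$sd * (lam_m * rep(f, each = length(im)) +
                         sqrt(1 - par$rho_in) * x[im, ])
  x[ib, ] <- lam_b * rep(f, each = length(ib)) +
    sqrt(1 - lam_b^2) * x[ib, ]
  x[nm$opt, opt] <- x[nm$opt, opt] + cfg$biomarker_shift
  x[nm$pess, pess] <- x[nm$pess, pess] + cfg$biomarker_shift
  x
}

#' Simulate an expression study with a planted tipping point
#'
#' Reference samples are drawn at baseline parameters; case samples per stage
#' follow the configured trajectory, with module correlation and standard
#' deviation peaking at the critical stage. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `study` (an [expression_study]) and `truth`, a record of
#'   the planted structure: `module_genes`, `boundary_genes`, `critical_stage`,
#'   `opt_gene`, `pess_gene`, and per-case-sample logical indicators
#'   `opt_carrier`, `pess_carrier` (named by sample ID).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nm <- .sim_gene_names(cfg)
  base_par <- list(rho_in = cfg$rho_in_base, rho_out = cfg$rho_out_base,
                   sd = cfg$sd_base)
  ref <- .sim_draw(cfg, nm, cfg$n_ref, base_par,
                   opt = logical(cfg$n_ref), pess = logical(cfg$n_ref))
  colnames(ref) <- sprintf("REF%03d", seq_len(cfg$n_ref))

  case_list <- list()
  ann <- list()
  opt_carrier <- pess_carrier <- logical(0)
  for (s in cfg$stages) {
    n <- cfg$n_per_stage
    opt <- stats::runif(n) < cfg$biomarker_prob
    pess <- stats::runif(n) < cfg$biomarker_prob
    x <- .sim_draw(cfg, nm, n, .stage_params(cfg, s), opt, pess)
    ids <- sprintf("S_%s_%02d", s, seq_len(n))
    colnames(x) <- ids
    case_list[[s]] <- x
    ann[[s]] <- data.frame(sample_id = ids, group = "case", stage = s,
                           stringsAsFactors = FALSE)
    opt_carrier <- c(opt_carrier, stats::setNames(opt, ids))
    pess_carrier <- c(pess_carrier, stats::setNames(pess, ids))
  }
  expr <- cbind(ref, do.call(cbind, case_list))
  annotations <- rbind(
    data.frame(sample_id = colnames(ref), group = "reference",
               stage = NA_character_, stringsAsFactors = FALSE),
    do.call(rbind, ann))
  list(study = expression_study(expr, annotations),
       truth = list(module_genes = nm$module, boundary_genes = nm$boundary,
                    critical_stage = cfg$critical_stage,
                    opt_gene = nm$opt, pess_gene = nm$pess,
                    opt_carrier = opt_carrier, pess_carrier = pess_carrier))
}

#' Simulate a PPI-style template network for the synthetic study
#'
#' The planted module is wired as a hub (first module gene linked to all
#' others) plus a ring over the remaining module genes; boundary genes bridge
#' to two module genes each; all other genes form a sparse random graph
#' (mean degree about 3), and any isolated node is attached to a random
#' partner so every node has degree >= 1. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [gene_network] on all `cfg$n_genes` genes.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  nm <- .sim_gene_names(cfg)
  mod <- nm$module
  edges <- cbind(mod[1], mod[-1])                         # hub
  if (length(mod) > 3) {
    ring <- mod[-1]
    edges <- rbind(edges, cbind(ring, c(ring[-1], ring[1])))
  }
  for (b in nm$boundary) {
    to <- sample(mod, 2)
    edges <- rbind(edges, cbind(b, to))
  }
  others <- c(nm$opt, nm$pess, nm$background)
  pool <- c(others, nm$boundary)
  # each unordered pair gets two chances in the loop below, so halve the rate
  p_edge <- min(1, cfg$bg_degree / 2 / max(1, length(pool) - 1))
  for (g in others) {
    partners <- pool[pool != g][stats::runif(length(pool) - 1) < p_edge]
    if (length(partners) == 0) partners <- sample(pool[pool != g], 2)
    edges <- rbind(edges, cbind(g, partners))
  }
  net <- gene_network(edges)
  lonely <- setdiff(nm$all, net$nodes)
  if (length(lonely) > 0) {
    extra <- cbind(lonely, sample(net$nodes, length(lonely), replace = TRUE))
    net <- gene_network(rbind(as.matrix(net$edges), extra))
  }
  net
}

#' Simulate survival outcomes for the synthetic study
#'
#' Exponential survival times with baseline hazard `log(2) / median_survival`.
#' The hazard is multiplied by `survival_hazard_ratio` for samples at or
#' after the planted critical stage and again for samples positive for the
#' pessimistic biomarker, and divided by it for samples positive for the
#' optimistic biomarker. Biomarker positivity is the sample's carrier
#' indicator from the `truth` record by default; when the realized LNE gene
#' sets are supplied via `sets`, positivity is actual membership of the
#' planted gene in the sample's set, so survival is linked to exactly the
#' stratification that [classify_biomarkers()] tests. Each record is
#' independently censored with probability `censoring_rate` (censoring time
#' uniform on (0, event time)). Deterministic under `cfg$seed`.
#'
#' @param truth the `truth` record from [simulate_study()].
#' @param samples data.frame of case samples with columns `sample_id`,
#'   `stage` (see [case_samples()]).
#' @param cfg the [sim_config()].
#' @param sets optional list of `lne_gene_set` objects (see [lne_genes()]);
#'   when given, biomarker positivity is realized set membership.
#' @return clinical data.frame with columns `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(truth, samples, cfg, sets = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  h0 <- log(2) / cfg$median_survival
  hr <- cfg$survival_hazard_ratio
  at_after <- match(samples$stage, cfg$stages) >=
    match(cfg$critical_stage, cfg$stages)
  if (is.null(sets)) {
    opt <- truth$opt_carrier[samples$sample_id]
    pess <- truth$pess_carrier[samples$sample_id]
  } else {
    ids <- vapply(sets, `[[`, character(1), "sample_id")
    opt <- vapply(sets, function(s) truth$opt_gene %in% s$genes,
                  logical(1))[match(samples$sample_id, ids)]
    pess <- vapply(sets, function(s) truth$pess_gene %in% s$genes,
                   logical(1))[match(samples$sample_id, ids)]
  }
  opt[is.na(opt)] <- FALSE; pess[is.na(pess)] <- FALSE
  hazard <- h0 * hr^(at_after + pess - opt)
  time <- stats::rexp(nrow(samples), rate = hazard)
  cens <- stats::runif(nrow(samples)) < cfg$censoring_rate
  obs <- ifelse(cens, stats::runif(nrow(samples), 0, time), time)
  data.frame(sample_id = samples$sample_id, time = obs,
             event = as.integer(!cens), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a synthetic study to disk in the formats the readers consume
#'
#' Writes `expression.tsv`, `annotations.tsv`, `clinical.tsv` and
#' `network.tsv` (edge list with a unit-scale score column) under `dir`, so
#' the command-line pipeline round-trips on synthetic data.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named list of the four file paths, invisibly; the simulated
#'   objects are attached as attribute `"objects"`.
#' @export
write_synthetic_study <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(cfg)
  net <- simulate_network(cfg)
  clin <- simulate_survival(sim$truth, case_samples(sim$study), cfg)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                clinical = file.path(dir, "clinical.tsv"),
                network = file.path(dir, "network.tsv"))
  write_expression(sim$study$expr, paths$expression)
  utils::write.table(sim$study$samples, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(clin, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(protein1 = net$edges$from, protein2 = net$edges$to,
               combined_score = 1),
    paths$network, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(paths, "objects") <- list(sim = sim, network = net, clinical = clin)
  invisible(paths)
}
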