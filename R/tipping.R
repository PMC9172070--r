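#' Stage-wise aggregation of LNE scores
#'
#' Averages the global LNE score of case samples within each clinical stage,
#' in the user-supplied stage order. Stage ordering is clinical (e.g.
#' I < II < IIIA < IIIB < IV), not lexicographic, so the caller must supply
#' it. Stages with no samples are dropped with a warning.
#'
#' @param scores list of `sample_score` objects (see [score_cohort()]).
#' @param stage_order character vector giving the clinical ordering of all
#'   stage labels.
#' @return object of class `stage_curve`: data.frame with columns `stage`,
#'   `n`, `mean_score`, in stage order.
#' @export
stage_curve <- function(scores, stage_order) {
  tab <- score_table(scores)
  unknown <- setdiff(unique(tab$stage), stage_order)
  if (length(unknown) > 0)
    stop("stage labels not in stage_order: ", paste(unknown, collapse = ", "))
  n <- vapply(stage_order, function(s) sum(tab$stage == s), numeric(1))
  if (any(n == 0))
    warning("dropping empty stages: ", paste(stage_order[n == 0], collapse = ", "))
  keep <- stage_order[n > 0]
  if (length(keep) < 2)
    stop("need at least 2 populated stages, got ", length(keep))
  mean_score <- vapply(keep, function(s) mean(tab$global_dE[tab$stage == s]),
                       numeric(1))
  structure(data.frame(stage = keep, n = n[keep], mean_score = mean_score,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("stage_curve", "data.frame"))
}

#' Call the critical transition stage
#'
#' The tipping point is read off the stage curve either as the stage with the
#' maximal mean LNE score (`"peak"`, the default: in the published cohorts
#' the score maximum coincides with the called critical stage) or as the
#' stage with the largest increase over its predecessor (`"max_increase"`).
#' Ties are broken toward the earlier stage (earliest warning).
#'
#' @param curve a [stage_curve()].
#' @param method `"peak"` or `"max_increase"`.
#' @return the called stage label.
#' @export
call_transition <- function(curve, method = c("peak", "max_increase")) {
  stopifnot(inherits(curve, "stage_curve"))
  method <- match.arg(method)
  if (nrow(curve) < 2) stop("stage curve must have at least 2 stages")
  if (method == "peak") {
    curve$stage[which.max(curve$mean_score)]   # which.max takes the first tie
  } else {
    inc <- diff(curve$mean_score)
    curve$stage[which.max(inc) + 1L]
  }
}

#' Compare survival before vs. after the transition
#'
#' Splits case samples into a "before" group (stages up to and including the
#' transition stage) and an "after" group (later stages), then runs the
#' two-group log-rank test. Samples without clinical records are dropped with
#' a warning.
#'
#' @param scores list of `sample_score` objects.
#' @param transition transition stage label (see [call_transition()]).
#' @param stage_order clinical stage ordering.
#' @param clinical data.frame with columns `sample_id`, `time`, `event`.
#' @return list with `transition`, `before_n`, `after_n`, `statistic`,
#'   `p_value`, `observed`, `expected`.
#' @export
before_after_survival <- function(scores, transition, stage_order, clinical) {
  if (!transition %in% stage_order) stop("unknown transition stage: ", transition)
  tab <- score_table(scores)
  drop <- !tab$sample_id %in% clinical$sample_id
  if (any(drop)) {
    warning(sum(drop), " scored samples lack clinical records and were dropped")
    tab <- tab[!drop, ]
  }
  cut <- match(transition, stage_order)
  before <- tab$sample_id[match(tab$stage, stage_order) <= cut]
  after <- tab$sample_id[match(tab$stage, stage_order) > cut]
  if (length(before) == 0 || length(after) == 0)
    stop("empty before/after group (before = ", length(before),
         ", after = ", length(after), ")")
  ca <- clinical[match(before, clinical$sample_id), ]
  cb <- clinical[match(after, clinical$sample_id), ]
  lr <- logrank_test(ca$time, ca$event, cb$time, cb$event)
  list(transition = transition, before_n = length(before),
       after_n = length(after), statistic = lr$statistic,
       p_value = lr$p_value, observed = lr$observed, expected = lr$expected)
}

#' Plot the stage curve
#'
#' @param x a [stage_curve()].
#' @param transition optional stage label to mark.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.stage_curve <- function(x, transition = NULL, ...) {
  graphics::plot(seq_len(nrow(x)), x$mean_score, type = "b", xaxt = "n",
                 xlab = "stage", ylab = "mean global LNE score", pch = 19, ...)
  graphics::axis(1, at = seq_len(nrow(x)), labels = x$stage)
  if (!is.null(transition))
    graphics::abline(v = match(transition, x$stage), lty = 2, col = "red")
  invisible(x)
}
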