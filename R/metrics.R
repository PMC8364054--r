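# Benchmark-style evaluation: scoring, ranking, docking and screening power
# with percentile-bootstrap confidence intervals, following the conventions
# of the comparative assessment of scoring functions (CASF).

#' Scored prediction set
#'
#' @param ids identifiers.
#' @param y experimental affinities, pK units.
#' @param yhat predicted affinities, pK units.
#' @param class_of optional target-class label per entry (ranking power).
#' @return an object of class `scored_set`.
#' @export
scored_set <- function(ids, y, yhat, class_of = NULL) {
  n <- length(ids)
  stopifnot(n >= 2, length(y) == n, length(yhat) == n)
  if (!is.null(class_of)) stopifnot(length(class_of) == n)
  structure(list(ids = as.character(ids), y = as.numeric(y),
                 yhat = as.numeric(yhat), class_of = class_of),
            class = "scored_set")
}

.pearson <- function(y, yhat) {
  # printed product-moment formula; errors (rather than NA) on degenerate
  # input so a constant predictor can never silently score 0
  dy <- y - mean(y)
  dh <- yhat - mean(yhat)
  sy <- sqrt(sum(dy^2))
  sh <- sqrt(sum(dh^2))
  if (sy == 0 || sh == 0)
    stop("Pearson correlation undefined for a constant vector")
  sum(dh * dy) / (sh * sy)
}

#' Scoring power: Pearson correlation and RMSE
#'
#' @param s a [scored_set()].
#' @return list with `pearson_r` and `rmse` (pK units).
#' @export
scoring_power <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  list(pearson_r = .pearson(s$y, s$yhat),
       rmse = sqrt(mean((s$yhat - s$y)^2)))
}

#' Percentile bootstrap confidence interval
#'
#' Paired resampling with replacement under `seed`; a replicate on which the
#' metric is undefined (e.g. a constant resample for a correlation) is
#' redrawn, up to 100 attempts per replicate.
#'
#' @param metric function of a [scored_set()] returning one number.
#' @param s a [scored_set()].
#' @param n_rep bootstrap replicates (benchmark convention: 10000).
#' @param level interval mass (benchmark convention: 0.90).
#' @param seed integer seed.
#' @return list with `lo`, `hi` and the replicate vector `boot`.
#' @export
bootstrap_ci <- function(metric, s, n_rep = 10000, level = 0.90, seed = 1L) {
  stopifnot(inherits(s, "scored_set"), n_rep >= 1, level > 0, level < 1)
  n <- length(s$y)
  boot <- withr::with_seed(seed, vapply(seq_len(n_rep), function(rep) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      rs <- s
      rs$ids <- s$ids[idx]
      rs$y <- s$y[idx]
      rs$yhat <- s$yhat[idx]
      if (!is.null(s$class_of)) rs$class_of <- s$class_of[idx]
      v <- tryCatch(metric(rs), error = function(e) NULL)
      if (!is.null(v) && is.finite(v)) return(v)
    }
    stop("bootstrap replicate undefined after 100 redraws")
  }, 0))
  a <- (1 - level) / 2
  q <- stats::quantile(boot, c(a, 1 - a), names = FALSE)
  list(lo = q[1], hi = q[2], boot = boot)
}

#' Predictive index
#'
#' Weighted pairwise concordance: weights `|y_j - y_i|`, each pair scoring
#' +1 when the predicted and experimental differences agree in sign, -1 when
#' they disagree, 0 when the predicted difference is zero.
#'
#' @param y experimental values.
#' @param yhat predicted values.
#' @return PI in \[-1, 1\].
#' @export
predictive_index <- function(y, yhat) {
  n <- length(y)
  stopifnot(n >= 2, length(yhat) == n)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    w <- abs(y[j] - y[i])
    cij <- sign(y[j] - y[i]) * sign(yhat[j] - yhat[i])
    num <- num + sum(w * cij)
    den <- den + sum(w)
  }
  if (den == 0) stop("predictive index undefined: all experimental values tied")
  num / den
}

#' Ranking power within target classes
#'
#' Spearman and Kendall (tau-b, tie-corrected) rank correlations and the
#' predictive index are computed inside each target class and averaged
#' across classes. Classes with fewer than two members are excluded with a
#' warning.
#'
#' @param s a [scored_set()] with non-`NULL` `class_of`.
#' @return list with `spearman`, `kendall`, `pi` (cross-class means) and the
#'   `per_class` data.frame.
#' @export
ranking_power <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  if (is.null(s$class_of)) stop("ranking power requires class labels")
  classes <- split(seq_along(s$y), s$class_of)
  small <- names(classes)[lengths(classes) < 2L]
  if (length(small)) {
    warning("excluding size-1 class(es): ", paste(small, collapse = ", "))
    classes <- classes[lengths(classes) >= 2L]
  }
  if (length(classes) == 0L) stop("no class with >= 2 members")
  per <- do.call(rbind, lapply(names(classes), function(cl) {
    idx <- classes[[cl]]
    data.frame(class_of = cl,
               n = length(idx),
               spearman = stats::cor(s$y[idx], s$yhat[idx], method = "spearman"),
               kendall = stats::cor(s$y[idx], s$yhat[idx], method = "kendall"),
               pi = predictive_index(s$y[idx], s$yhat[idx]))
  }))
  list(spearman = mean(per$spearman), kendall = mean(per$kendall),
       pi = mean(per$pi), per_class = per)
}

#' Decoy-pose set for one target
#'
#' @param target_id identifier.
#' @param poses data.frame with columns `pose_id`, `rmsd` (Angstrom from the
#'   crystallographic mode) and `score` (pK; higher is better).
#' @return an object of class `decoy_set`.
#' @export
decoy_set <- function(target_id, poses) {
  stopifnot(all(c("pose_id", "rmsd", "score") %in% names(poses)),
            nrow(poses) >= 3, all(is.finite(poses$score)))
  structure(list(target_id = target_id, poses = poses), class = "decoy_set")
}

#' Docking power: top-k success rates
#'
#' A target counts as a top-k success when any of its k best-scored poses
#' (highest pK; ties broken by the stable pose_id order and flagged) lies
#' within `rmsd_cut` of the crystallographic mode. Rates are percentages
#' over targets; top1 <= top2 <= top3 by construction.
#'
#' @param sets list of [decoy_set()] objects.
#' @param rmsd_cut success threshold, Angstrom (benchmark convention: 2).
#' @return list with `top1`, `top2`, `top3` (percent), per-target detail and
#'   `n_tied_targets`.
#' @export
docking_power <- function(sets, rmsd_cut = 2.0) {
  stopifnot(length(sets) >= 1)
  detail <- do.call(rbind, lapply(sets, function(ds) {
    stopifnot(inherits(ds, "decoy_set"))
    p <- ds$poses
    ord <- order(-p$score, p$pose_id)
    tied <- anyDuplicated(p$score) > 0
    ok <- p$rmsd[ord] <= rmsd_cut
    data.frame(target_id = ds$target_id,
               top1 = any(ok[1]), top2 = any(ok[1:min(2, length(ok))]),
               top3 = any(ok[1:min(3, length(ok))]), tied = tied)
  }))
  list(top1 = 100 * mean(detail$top1),
       top2 = 100 * mean(detail$top2),
       top3 = 100 * mean(detail$top3),
       per_target = detail,
       n_tied_targets = sum(detail$tied))
}

#' Screening candidate pool for one target
#'
#' @param target_id identifier.
#' @param candidates data.frame with columns `ligand_id`, `score`,
#'   `is_true_binder`, `is_best_binder`.
#' @return an object of class `screening_set`.
#' @export
screening_set <- function(target_id, candidates) {
  stopifnot(all(c("ligand_id", "score", "is_true_binder", "is_best_binder")
                %in% names(candidates)))
  structure(list(target_id = target_id, candidates = candidates),
            class = "screening_set")
}

#' Screening power: enrichment and success rates
#'
#' Per target, candidates are ranked by score (descending, ties broken by
#' ligand_id) and the top `ceiling(alpha * N)` are examined.
#' `EF_alpha = TB_alpha / (alpha * TB_tot)` where `TB_alpha` counts true
#' binders in the top fraction and `TB_tot` all true binders; forward
#' success requires the best binder in the top fraction. Reverse screening
#' ranks, for each ligand present in several pools, the targets by that
#' ligand's score and succeeds when a target for which the ligand is a true
#' binder appears in the top fraction of targets. Targets without true
#' binders are skipped with a warning.
#'
#' @param sets list of [screening_set()] objects.
#' @param alphas top fractions, each in (0, 1\]; default 1%, 5%, 10%.
#' @return list with data.frames `forward` (alpha, success_rate percent,
#'   mean_ef) and `reverse` (alpha, success_rate percent), plus per-target
#'   EF detail.
#' @export
screening_power <- function(sets, alphas = c(0.01, 0.05, 0.10)) {
  stopifnot(length(sets) >= 1, all(alphas > 0), all(alphas <= 1))
  usable <- vapply(sets, function(ss) sum(ss$candidates$is_true_binder) > 0,
                   TRUE)
  if (any(!usable)) {
    warning(sum(!usable), " target(s) without true binders skipped")
    sets <- sets[usable]
  }
  if (length(sets) == 0L) stop("no usable screening target")
  per_target <- do.call(rbind, lapply(sets, function(ss) {
    cand <- ss$candidates
    ord <- order(-cand$score, cand$ligand_id)
    cand <- cand[ord, ]
    tb_tot <- sum(cand$is_true_binder)
    do.call(rbind, lapply(alphas, function(a) {
      ntop <- ceiling(a * nrow(cand))
      top <- cand[seq_len(ntop), ]
      data.frame(target_id = ss$target_id, alpha = a,
                 ef = sum(top$is_true_binder) / (a * tb_tot),
                 success = any(top$is_best_binder))
    }))
  }))
  forward <- do.call(rbind, lapply(alphas, function(a) {
    rows <- per_target[per_target$alpha == a, ]
    data.frame(alpha = a, success_rate = 100 * mean(rows$success),
               mean_ef = mean(rows$ef))
  }))
  # reverse screening: ligand-major ranking of targets
  lig_tab <- do.call(rbind, lapply(sets, function(ss)
    data.frame(target_id = ss$target_id, ss$candidates)))
  n_targets <- length(sets)
  by_lig <- split(lig_tab, lig_tab$ligand_id)
  by_lig <- by_lig[vapply(by_lig, function(d)
    nrow(d) >= 2L && any(d$is_true_binder), TRUE)]
  reverse <- do.call(rbind, lapply(alphas, function(a) {
    ntop <- ceiling(a * n_targets)
    if (length(by_lig) == 0L)
      return(data.frame(alpha = a, success_rate = NA_real_))
    succ <- vapply(by_lig, function(d) {
      ord <- order(-d$score, d$target_id)
      any(d$is_true_binder[ord][seq_len(min(ntop, nrow(d)))])
    }, TRUE)
    data.frame(alpha = a, success_rate = 100 * mean(succ))
  }))
  list(forward = forward, reverse = reverse, per_target = per_target)
}

#' Assemble a metrics report with bootstrap intervals
#'
#' Scoring (and, when class labels are present, ranking) power with
#' percentile-bootstrap confidence intervals in the benchmark's
#' `[lo, hi]` style.
#'
#' @param s a [scored_set()].
#' @param n_boot bootstrap replicates.
#' @param level interval mass.
#' @param seed integer seed.
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(s, n_boot = 10000, level = 0.90, seed = 1L) {
  sp <- scoring_power(s)
  ci_r <- bootstrap_ci(function(x) scoring_power(x)$pearson_r, s,
                       n_rep = n_boot, level = level, seed = seed)
  ci_rmse <- bootstrap_ci(function(x) scoring_power(x)$rmse, s,
                          n_rep = n_boot, level = level, seed = seed + 1L)
  rep <- list(n = length(s$y), level = level,
              pearson_r = list(point = sp$pearson_r,
                               lo = ci_r$lo, hi = ci_r$hi),
              rmse = list(point = sp$rmse, lo = ci_rmse$lo, hi = ci_rmse$hi))
  if (!is.null(s$class_of)) {
    rk <- ranking_power(s)
    rep$ranking <- list(spearman = rk$spearman, kendall = rk$kendall,
                        pi = rk$pi, per_class = rk$per_class)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(m) sprintf("%.3f [%.3f, %.3f]_CI%.0f%%",
                             m$point, m$lo, m$hi, 100 * x$level)
  cat("metrics report (n =", x$n, ")\n")
  cat("  Pearson r :", pct(x$pearson_r), "\n")
  cat("  RMSE (pK) :", pct(x$rmse), "\n")
  if (!is.null(x$ranking))
    cat(sprintf("  ranking   : spearman %.3f  kendall %.3f  PI %.3f\n",
                x$ranking$spearman, x$ranking$kendall, x$ranking$pi))
  invisible(x)
}
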