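test_that("scoring power matches hand arithmetic and degenerate handling", {
  s <- scored_set(letters[1:4], y = c(1, 2, 3, 4),
                  yhat = c(1.5, 1.5, 3.5, 3.5))
  sp <- scoring_power(s)
  # hand computation: sum(dh*dy) = 4, norms 2 and sqrt(5)
  expect_equal(sp$pearson_r, 4 / (2 * sqrt(5)), tolerance = 1e-12)
  expect_equal(sp$pearson_r, 0.894, tolerance = 1e-3)
  expect_equal(sp$rmse, 0.5)
  # perfect and anti-perfect predictors
  s2 <- scored_set(letters[1:4], 1:4, 1:4)
  expect_equal(scoring_power(s2)$pearson_r, 1)
  expect_equal(scoring_power(s2)$rmse, 0)
  s3 <- scored_set(letters[1:4], 1:4, -(1:4) + 10)
  expect_equal(scoring_power(s3)$pearson_r, -1)
  expect_error(scoring_power(scored_set(letters[1:3], 1:3, rep(2, 3))),
               "constant")
})

test_that("pearson is invariant to positive affine rescaling, rmse is not", {
  s <- scored_set(letters[1:6], y = c(2, 4, 5, 7, 8, 9),
                  yhat = c(2.5, 3.5, 5.5, 6.5, 8.5, 8.0))
  base <- scoring_power(s)
  s$yhat <- 2.3 * s$yhat + 1.1
  scaled <- scoring_power(s)
  expect_equal(scaled$pearson_r, base$pearson_r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(scaled$rmse, base$rmse)))
})

test_that("bootstrap intervals are deterministic, degenerate on perfect
           agreement, and roughly calibrated", {
  s <- scored_set(letters[1:10], 1:10, 1:10)
  ci <- bootstrap_ci(function(x) scoring_power(x)$pearson_r, s,
                     n_rep = 200, seed = 3L)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  s2 <- scored_set(sprintf("i%02d", 1:30),
                   y = withr::with_seed(1, stats::rnorm(30)),
                   yhat = withr::with_seed(2, stats::rnorm(30)))
  ci1 <- bootstrap_ci(function(x) scoring_power(x)$pearson_r, s2,
                      n_rep = 500, seed = 7L)
  ci2 <- bootstrap_ci(function(x) scoring_power(x)$pearson_r, s2,
                      n_rep = 500, seed = 7L)
  expect_identical(c(ci1$lo, ci1$hi), c(ci2$lo, ci2$hi))
  expect_lte(ci1$lo, ci1$hi)
  # coverage at reduced outer replication: true r from a known generator
  rho <- 0.8
  hits <- 0
  outer_reps <- 40
  for (rep in seq_len(outer_reps)) {
    withr::with_seed(1000 + rep, {
      x <- stats::rnorm(60)
      yy <- rho * x + sqrt(1 - rho^2) * stats::rnorm(60)
    })
    sb <- scored_set(sprintf("s%02d", 1:60), x, yy)
    ci <- bootstrap_ci(function(z) scoring_power(z)$pearson_r, sb,
                       n_rep = 400, level = 0.9, seed = rep)
    if (ci$lo <= rho && rho <= ci$hi) hits <- hits + 1
  }
  expect_gte(hits / outer_reps, 0.75)
})

test_that("ranking power: perfect, reversed, and adjacent-swap cases", {
  cls <- rep(c("t1", "t2"), each = 5)
  y <- c(1:5, 1:5)
  perfect <- ranking_power(scored_set(1:10, y, y + 0.1, cls))
  expect_equal(perfect$spearman, 1)
  expect_equal(perfect$kendall, 1)
  expect_equal(perfect$pi, 1)
  reversed <- ranking_power(scored_set(1:10, y, -y, cls))
  expect_equal(reversed$spearman, -1)
  expect_equal(reversed$kendall, -1)
  expect_equal(reversed$pi, -1)
  # one 5-member class, single adjacent swap at the top:
  # kendall 0.8, spearman 0.9, PI = (20 - 2)/20 = 0.9 from |y| weights
  swap <- ranking_power(scored_set(1:5, 1:5, c(1, 2, 3, 5, 4),
                                   rep("t", 5)))
  expect_equal(swap$kendall, 0.8)
  expect_equal(swap$spearman, 0.9)
  expect_equal(swap$pi, 0.9)
})

test_that("ranking metrics are invariant to monotone transforms; small
           classes excluded with warning", {
  cls <- rep(c("a", "b"), each = 5)
  withr::with_seed(5, {
    y <- stats::rnorm(10)
    yhat <- stats::rnorm(10)
  })
  base <- ranking_power(scored_set(1:10, y, yhat, cls))
  mono <- ranking_power(scored_set(1:10, y, exp(2 * yhat) + 3, cls))
  expect_equal(mono$spearman, base$spearman, tolerance = 1e-12)
  expect_equal(mono$kendall, base$kendall, tolerance = 1e-12)
  expect_equal(mono$pi, base$pi, tolerance = 1e-12)
  expect_warning(
    ranking_power(scored_set(1:11, c(y, 1), c(yhat, 1), c(cls, "c"))),
    "size-1")
})

test_that("docking power: closed cases and ordering invariant", {
  mk <- function(id, rank_of_good, n = 5) {
    rmsd <- rep(6, n)
    rmsd[rank_of_good] <- 0.5
    decoy_set(id, data.frame(pose_id = sprintf("p%d", 1:n),
                             rmsd = rmsd, score = n:1))
  }
  # good pose ranked 1st, 2nd, 4th across three targets
  dp <- docking_power(list(mk("t1", 1), mk("t2", 2), mk("t3", 4)))
  expect_equal(dp$top1, 100 / 3, tolerance = 1e-9)
  expect_equal(dp$top2, 200 / 3, tolerance = 1e-9)
  expect_equal(dp$top3, 200 / 3, tolerance = 1e-9)
  expect_true(dp$top1 <= dp$top2 && dp$top2 <= dp$top3)
  # all native-ranked-first -> 100/100/100; none under cut -> 0/0/0
  expect_equal(docking_power(list(mk("t", 1)))$top1, 100)
  bad <- decoy_set("t", data.frame(pose_id = c("a", "b", "c"),
                                   rmsd = c(3, 4, 5), score = 3:1))
  dp0 <- docking_power(list(bad))
  expect_equal(c(dp0$top1, dp0$top2, dp0$top3), c(0, 0, 0))
  # tie broken by pose_id, and flagged
  tied <- decoy_set("t", data.frame(pose_id = c("a", "b", "c"),
                                    rmsd = c(0.5, 6, 6),
                                    score = c(1, 1, 1)))
  dpt <- docking_power(list(tied))
  expect_equal(dpt$top1, 100)
  expect_identical(dpt$n_tied_targets, 1L)
})

test_that("screening power: printed-formula enrichment and edge cases", {
  # 1000 candidates, 10 true binders, 2 in the top 1% -> EF = 20
  n <- 1000
  cand <- data.frame(ligand_id = sprintf("L%04d", 1:n),
                     score = seq(n, 1) / n,
                     is_true_binder = FALSE, is_best_binder = FALSE)
  cand$is_true_binder[c(3, 7, seq(500, 507))] <- TRUE   # 10 total, 2 in top 10
  cand$is_best_binder[3] <- TRUE
  sp <- screening_power(list(screening_set("t", cand)), alphas = 0.01)
  expect_equal(sp$forward$mean_ef, 2 / (0.01 * 10))
  expect_equal(sp$forward$success_rate, 100)
  # all true binders ranked last -> EF 0 at small alpha
  cand2 <- cand
  cand2$is_true_binder <- c(rep(FALSE, n - 10), rep(TRUE, 10))
  cand2$is_best_binder <- c(rep(FALSE, n - 1), TRUE)
  sp2 <- screening_power(list(screening_set("t", cand2)), alphas = 0.01)
  expect_equal(sp2$forward$mean_ef, 0)
  expect_equal(sp2$forward$success_rate, 0)
  # EF bounded by 1/alpha
  expect_lte(sp$forward$mean_ef, 1 / 0.01)
  # target without binders skipped with warning
  cand3 <- cand
  cand3$is_true_binder <- FALSE
  expect_warning(
    screening_power(list(screening_set("a", cand), screening_set("b", cand3)),
                    alphas = 0.05),
    "skipped")
})

test_that("random scores give mean enrichment near 1", {
  sets <- lapply(1:20, function(t) {
    withr::with_seed(t, {
      n <- 400
      tb <- rep(FALSE, n)
      tb[sample(n, 40)] <- TRUE
      sc <- stats::rnorm(n)
    })
    best <- which(tb)[1]
    screening_set(sprintf("t%02d", t),
                  data.frame(ligand_id = sprintf("L%03d", 1:400), score = sc,
                             is_true_binder = tb,
                             is_best_binder = seq_len(400) == best))
  })
  sp <- screening_power(sets, alphas = c(0.05, 0.10))
  expect_equal(sp$forward$mean_ef[1], 1, tolerance = 0.25)
  expect_equal(sp$forward$mean_ef[2], 1, tolerance = 0.25)
})

test_that("reverse screening ranks targets per ligand", {
  # 4 targets share 10 ligands; ligand Lk binds target t1 with high score
  mk <- function(tid, scores, binder_idx) {
    screening_set(tid, data.frame(
      ligand_id = sprintf("L%02d", 1:10), score = scores,
      is_true_binder = seq_len(10) %in% binder_idx,
      is_best_binder = seq_len(10) == binder_idx[1]))
  }
  sets <- list(mk("t1", c(9, 1, 1, 1, 1, 1, 1, 1, 1, 1), 1),
               mk("t2", rep(0.5, 10), 2),
               mk("t3", rep(0.4, 10), 3),
               mk("t4", rep(0.3, 10), 4))
  sp <- screening_power(sets, alphas = 0.25)
  # ligand L01: top ceil(0.25*4) = 1 target by score is t1, its true target
  expect_true(is.finite(sp$reverse$success_rate))
  expect_gte(sp$reverse$success_rate, 0)
})

test_that("metrics_report assembles point estimates with intervals", {
  withr::with_seed(11, {
    y <- stats::rnorm(40, 6, 1.5)
    yhat <- y + stats::rnorm(40, 0, 0.8)
  })
  rep <- metrics_report(scored_set(sprintf("c%02d", 1:40), y, yhat),
                        n_boot = 300, seed = 2L)
  expect_lte(rep$pearson_r$lo, rep$pearson_r$point)
  expect_gte(rep$pearson_r$hi, rep$pearson_r$point)
  expect_lte(rep$rmse$lo, rep$rmse$point)
  expect_gte(rep$rmse$hi, rep$rmse$point)
})
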