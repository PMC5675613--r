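test_that("roc_auc handles perfect separation, inversion, and input errors", {
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 1, 0))$auc, 0)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "at least one")
})

test_that("roc_auc equals the pairwise-concordance oracle with ties", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    scores <- sample(round(rnorm(n), 1))     # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    roc <- roc_auc(scores, labels)
    expect_equal(roc$auc, oracle_concordance_auc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(roc_trapezoid(roc), roc$auc, tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]),
                 c(1, 1))
  }
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, base)
  expect_equal(roc_auc(5 * scores - 3, labels)$auc, base)
  expect_equal(roc_auc(rank(scores), labels)$auc, base)
})

make_tiny_dataset <- function(seed = 8, n_mirnas = 14, n_diseases = 8) {
  d <- generate_synthetic(synthetic_spec(
    n_mirnas = n_mirnas, n_diseases = n_diseases, n_clusters = 2,
    n_tissues = 6, assoc_per_cluster = 2, seed = seed
  ))
  as_mda_dataset(d)
}

test_that("loocv degenerate scorers give AUC 0.5 (all ties) and 1 (oracle)", {
  ds <- make_tiny_dataset()
  # scoring with the training matrix itself: held-out pair scores 0, tying
  # with every candidate
  echo_scorer <- function(A, SM_mir, SM_dis, config) A
  expect_equal(loocv(ds, echo_scorer)$auc, 0.5)

  # an oracle that knows the full association matrix ranks every held-out
  # pair above all candidates
  full_A <- ds$A
  cheat_scorer <- function(A, SM_mir, SM_dis, config) full_A
  expect_equal(loocv(ds, cheat_scorer)$auc, 1)
})

test_that("loocv ROC trapezoid equals the mean round concordance", {
  ds <- make_tiny_dataset(seed = 12)
  res <- loocv(ds)
  expect_equal(roc_trapezoid(res$roc), res$auc, tolerance = 1e-12)
  expect_equal(res$roc$auc, res$auc)
  expect_equal(nrow(res$holdouts), sum(ds$A))
})

test_that("a random scorer scores near 0.5 in LOOCV", {
  ds <- make_tiny_dataset(seed = 19)
  rng_scorer <- function(A, SM_mir, SM_dis, config) {
    matrix(runif(length(A)), nrow(A), ncol(A), dimnames = dimnames(A))
  }
  res <- withr::with_seed(7, loocv(ds, rng_scorer))
  n_rounds <- nrow(res$holdouts)
  se <- sqrt(1 / 12 / n_rounds)   # concordance of one round ~ Uniform(0,1)
  expect_lt(abs(res$auc - 0.5), 3 * se)
})

test_that("kfold with folds = N reproduces loocv and is seed-deterministic", {
  ds <- make_tiny_dataset(seed = 23)
  n_known <- sum(ds$A)
  lo <- loocv(ds)
  kf <- kfold_cv(ds, folds = n_known, repetitions = 1, seed = 1)
  expect_equal(kf$per_repetition_auc, lo$auc, tolerance = 1e-12)

  a <- kfold_cv(ds, folds = 4, repetitions = 3, seed = 99)
  b <- kfold_cv(ds, folds = 4, repetitions = 3, seed = 99)
  expect_identical(a, b)
  expect_length(a$per_repetition_auc, 3)
  expect_equal(a$mean_auc, mean(a$per_repetition_auc))
  expect_equal(a$sd_auc, sd(a$per_repetition_auc))
})

test_that("candidate ranking sorts by score with stable ties and exclusions", {
  SS <- matrix(c(0.9, 0.1, 0.5), 3, 1,
               dimnames = list(c("m1", "m2", "m3"), "d1"))
  rk <- rank_disease_candidates(SS, "d1", top_k = 3)
  expect_equal(rk$mirna, c("m1", "m3", "m2"))
  expect_equal(rk$rank, 1:3)

  known <- matrix(c(1, 0, 0), 3, 1, dimnames = dimnames(SS))
  rk2 <- rank_disease_candidates(SS, "d1", top_k = 3, exclude_known = TRUE,
                                 known = known)
  expect_equal(rk2$mirna, c("m3", "m2"))

  expect_error(rank_disease_candidates(SS, "nope"), "unknown disease")

  # ties keep input order; top_k truncates; scores non-increasing
  SS3 <- matrix(c(0.4, 0.4, 0.4, 0.7), 4, 1,
                dimnames = list(sprintf("m%d", 1:4), "d1"))
  rk3 <- rank_disease_candidates(SS3, "d1", top_k = 25)
  expect_equal(rk3$mirna, c("m4", "m1", "m2", "m3"))
  expect_equal(nrow(rk3), 4)
  expect_true(all(diff(rk3$score) <= 0))
})

test_that("tidiers and plots expose results as tibbles and ggplots", {
  ds <- make_tiny_dataset(seed = 3)
  sc <- score_dataset(ds$A, ds$SM_mir, ds$SM_dis)
  td <- tidy(sc, known = ds$A)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(sc$SS))
  expect_true(all(diff(td$score) <= 0))
  expect_equal(names(td), c("mirna", "disease", "score", "is_known"))
  expect_equal(glance(sc)$n_mirnas, nrow(ds$A))

  lo <- loocv(ds)
  expect_s3_class(tidy(lo), "tbl_df")
  expect_equal(glance(lo)$auc, lo$auc)
  expect_s3_class(autoplot(lo), "ggplot")
  expect_s3_class(autoplot(lo$roc), "ggplot")

  cv <- kfold_cv(ds, folds = 3, repetitions = 2, seed = 4)
  expect_equal(nrow(tidy(cv)), 2)
  expect_equal(glance(cv)$mean_auc, cv$mean_auc)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(plot_score_heatmap(sc), "ggplot")
})
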