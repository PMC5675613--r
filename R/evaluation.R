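#' ROC curve and AUC from scores and binary labels
#'
#' The AUC is the pairwise-concordance (Mann-Whitney) statistic: the fraction
#' of positive-negative score pairs ranked concordantly, ties counting 0.5.
#' The curve sweeps thresholds over the distinct scores in descending order;
#' tied scores move as one block, so tie groups appear as diagonal segments
#' and the trapezoidal area under the curve equals the concordance AUC.
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels Binary vector (0/1 or logical) of the same length, with at
#'   least one positive and one negative.
#' @return An object of class `mda_roc`: list with `thresholds` (descending),
#'   `fpr`, `tpr` (both starting at 0 and ending at 1), and `auc`.
#' @examples
#' roc_auc(c(3, 2, 1), c(1, 1, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc needs at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), 0)
  structure(
    list(
      thresholds = c(Inf, thr),
      fpr = c(0, fp / n_neg),
      tpr = c(0, tp / n_pos),
      auc = auc
    ),
    class = "mda_roc"
  )
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc An `mda_roc` object.
#' @return The trapezoidal integral of tpr over fpr.
#' @export
roc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' @export
print.mda_roc <- function(x, ...) {
  cat("<mda_roc> AUC =", format(x$auc, digits = 6), "over",
      length(x$fpr), "curve points\n")
  invisible(x)
}

#' Bundle an association matrix with its similarity matrices
#'
#' @param A Binary association matrix (miRNAs x diseases) with dimnames.
#' @param SM_mir,SM_dis Similarity matrices or `mda_similarity` objects.
#' @return An `mda_dataset` list.
#' @export
mda_dataset <- function(A, SM_mir, SM_dis) {
  SM_mir <- as_similarity_matrix(SM_mir)
  SM_dis <- as_similarity_matrix(SM_dis)
  stopifnot(nrow(A) == nrow(SM_mir), ncol(A) == nrow(SM_dis))
  structure(list(A = A, SM_mir = SM_mir, SM_dis = SM_dis),
            class = "mda_dataset")
}

as_score_matrix <- function(x) {
  if (inherits(x, "mda_scores")) x$SS else x
}

#' The diffusion scorer, in the shared scorer contract
#'
#' All evaluation harnesses take a scorer: a function
#' `(A_train, SM_mir, SM_dis, config) -> score matrix`. This is the two-way
#' diffusion model in that form; the baselines in [baseline_scorer()] use the
#' same contract.
#'
#' @param A_train Training association matrix (held-out pairs zeroed).
#' @param SM_mir,SM_dis Similarity matrices.
#' @param config An [mda_config()].
#' @return A numeric score matrix, same shape as `A_train`.
#' @export
diffusion_scorer <- function(A_train, SM_mir, SM_dis, config = mda_config()) {
  score_dataset(A_train, SM_mir, SM_dis, config)$SS
}

# concordance of one held-out score against the candidate pool
holdout_concordance <- function(s, candidate_scores) {
  (sum(candidate_scores < s) + 0.5 * sum(candidate_scores == s)) /
    length(candidate_scores)
}

#' Leave-one-out cross-validation of a scorer
#'
#' Each known association is removed from the training matrix in turn, the
#' scorer is re-run, and the held-out pair's score is compared with the
#' scores of every candidate pair (pairs absent from the FULL known set; a
#' held-out positive never competes against other training positives). The
#' per-round concordance is the fraction of candidates scored strictly below
#' the held-out pair, ties counting 0.5; the overall AUC is the mean over
#' rounds, and the ROC curve is the staircase of the held-out pairs'
#' normalised candidate ranks, whose trapezoidal area equals that mean.
#'
#' @param dataset An [mda_dataset()].
#' @param scorer A scorer function (see [diffusion_scorer()]).
#' @param config An [mda_config()].
#' @return An object of class `mda_loocv`: `auc`, `roc` (`mda_roc`),
#'   `holdouts` (tibble: mirna, disease, score, concordance), `n_candidates`.
#' @export
loocv <- function(dataset, scorer = diffusion_scorer, config = mda_config()) {
  A <- dataset$A
  known <- which(A == 1)
  if (length(known) < 2) stop("need >= 2 known associations", call. = FALSE)
  cand <- which(A == 0)
  if (length(cand) == 0) stop("no candidate pairs to rank against", call. = FALSE)

  conc <- vapply(seq_along(known), function(r) {
    k <- known[r]
    At <- A
    At[k] <- 0
    SS <- as_score_matrix(scorer(At, dataset$SM_mir, dataset$SM_dis, config))
    if (any(!is.finite(SS))) {
      stop("scorer returned non-finite scores in LOOCV round ", r,
           call. = FALSE)
    }
    holdout_concordance(SS[k], SS[cand])
  }, 0)

  ij <- arrayInd(known, dim(A))
  structure(
    list(
      auc = mean(conc),
      roc = roc_from_holdout_ranks(1 - conc),
      holdouts = tibble::tibble(
        mirna = rownames(A)[ij[, 1]],
        disease = colnames(A)[ij[, 2]],
        concordance = conc
      ),
      n_candidates = length(cand)
    ),
    class = "mda_loocv"
  )
}

# Staircase ROC over held-out normalised ranks u = 1 - concordance: at
# candidate-rank threshold q the FPR is q and the TPR is the fraction of
# held-out pairs with u <= q. Trapezoid area = mean(1 - u) exactly.
roc_from_holdout_ranks <- function(u) {
  n <- length(u)
  uk <- sort(unique(u))
  Fk <- vapply(uk, function(q) mean(u <= q), 0)
  fpr <- c(0, rep(uk, each = 2), 1)
  tpr <- c(0, 0, rep(Fk, each = 2))[seq_along(fpr)]
  roc <- structure(
    list(thresholds = 1 - fpr, fpr = fpr, tpr = tpr, auc = mean(1 - u)),
    class = "mda_roc"
  )
  roc
}

#' @export
print.mda_loocv <- function(x, ...) {
  cat("<mda_loocv>", nrow(x$holdouts), "rounds, AUC =",
      format(x$auc, digits = 6), "\n")
  invisible(x)
}

#' Repeated k-fold cross-validation of a scorer
#'
#' Per repetition, the known associations are shuffled (seed + repetition
#' index) and split into folds whose sizes differ by at most one. Each fold is
#' zeroed in the training matrix in turn; every held-out pair is scored
#' against the candidate pool exactly as in [loocv()]. A fold's AUC is the
#' mean concordance of its held-out pairs, a repetition's AUC the mean over
#' folds. With folds equal to the number of known associations this
#' reproduces the LOOCV AUC.
#'
#' @param dataset An [mda_dataset()].
#' @param scorer A scorer function.
#' @param folds Number of folds (>= 2, <= number of known pairs).
#' @param repetitions Number of independent re-splits.
#' @param seed Base seed; repetition r uses `seed + r`.
#' @param config An [mda_config()].
#' @return An object of class `mda_cv`: `per_repetition_auc`, `mean_auc`,
#'   `sd_auc` (sample sd; `NA` for a single repetition), `folds`,
#'   `repetitions`, `seed`.
#' @export
kfold_cv <- function(dataset, scorer = diffusion_scorer,
                     folds = 5, repetitions = 20, seed = 42,
                     config = mda_config()) {
  A <- dataset$A
  known <- which(A == 1)
  stopifnot(folds >= 2, length(known) >= folds)
  cand <- which(A == 0)

  rep_auc <- vapply(seq_len(repetitions), function(r) {
    perm <- withr::with_seed(seed + r, sample(known))
    fold_id <- rep(seq_len(folds), length.out = length(perm))
    fold_auc <- vapply(seq_len(folds), function(f) {
      held <- perm[fold_id == f]
      At <- A
      At[held] <- 0
      SS <- as_score_matrix(scorer(At, dataset$SM_mir, dataset$SM_dis, config))
      if (any(!is.finite(SS))) {
        stop("scorer returned non-finite scores in repetition ", r,
             ", fold ", f, call. = FALSE)
      }
      cs <- SS[cand]
      mean(vapply(held, function(k) holdout_concordance(SS[k], cs), 0))
    }, 0)
    mean(fold_auc)
  }, 0)

  structure(
    list(
      per_repetition_auc = rep_auc,
      mean_auc = mean(rep_auc),
      sd_auc = if (repetitions > 1) stats::sd(rep_auc) else NA_real_,
      folds = as.integer(folds),
      repetitions = as.integer(repetitions),
      seed = as.integer(seed)
    ),
    class = "mda_cv"
  )
}

#' @export
print.mda_cv <- function(x, ...) {
  cat("<mda_cv>", x$repetitions, "x", x$folds, "-fold CV: mean AUC =",
      format(x$mean_auc, digits = 6), "sd =", format(x$sd_auc, digits = 3),
      "\n")
  invisible(x)
}

#' Rank candidate miRNAs for one disease
#'
#' miRNAs sorted by their score for the disease, descending, ties broken by
#' input (row) order. In case-study mode the model is trained on all data and
#' the already-known miRNAs are excluded so the list contains candidates only.
#'
#' @param scores An `mda_scores` object or score matrix with dimnames.
#' @param disease_id Disease to rank for (must be a column).
#' @param top_k Number of rows to return (default 25).
#' @param exclude_known Drop miRNAs already associated with the disease.
#' @param known Binary association matrix; required when `exclude_known`.
#' @return A tibble (rank, mirna, score) with `min(top_k, candidates)` rows.
#' @export
rank_disease_candidates <- function(scores, disease_id, top_k = 25,
                                    exclude_known = FALSE, known = NULL) {
  SS <- as_score_matrix(scores)
  if (!disease_id %in% colnames(SS)) {
    stop("unknown disease id: ", disease_id, call. = FALSE)
  }
  s <- SS[, disease_id]
  keep <- rep(TRUE, length(s))
  if (exclude_known) {
    if (is.null(known)) {
      stop("exclude_known = TRUE requires the known association matrix",
           call. = FALSE)
    }
    keep <- known[, disease_id] == 0
  }
  ids <- rownames(SS)[keep]
  s <- s[keep]
  ord <- order(-s)                       # stable: ties keep input order
  n <- min(top_k, length(s))
  tibble::tibble(
    rank = seq_len(n),
    mirna = ids[ord][seq_len(n)],
    score = unname(s[ord][seq_len(n)])
  )
}
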