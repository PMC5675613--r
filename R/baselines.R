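#' Collaborative-filtering and Katz baseline scorers
#'
#' Reference scorers the diffusion model is benchmarked against, built from
#' the standard textbook definitions (treating miRNAs as users, diseases as
#' items, the association matrix as the rating matrix):
#'
#' * `user_based_cf`: `score(i,j) = sum_k SM_mir(i,k) A(k,j) / sum_k |SM_mir(i,k)|`,
#'   sums over `k != i`, 0/0 -> 0.
#' * `item_based_cf`: `score(i,j) = sum_l A(i,l) SM_dis(l,j) / sum_l |SM_dis(l,j)|`,
#'   sums over `l != j`, 0/0 -> 0.
#' * `neighbor_based_cf`: `lambda * user + (1 - lambda) * item`, entrywise.
#' * `katz_scores`: walk counting on the heterogeneous network
#'   `H = [[SM_mir, A], [t(A), SM_dis]]` - the sum of `katz_beta^l * H^l`
#'   over walk lengths `l` up to `katz_max_length` (from `l = 1` when
#'   `include_direct`, else `l = 2`), keeping the upper-right miRNA x disease
#'   block.
#'
#' @param A Binary association matrix (miRNAs x diseases).
#' @param SM_mir,SM_dis Similarity matrices or `mda_similarity` objects.
#' @param lambda Weight of the user-based score in `neighbor_based_cf`.
#' @param katz_beta Walk damping factor (> 0).
#' @param max_length Longest counted walk (integer >= 2).
#' @param include_direct Count the direct edge (length-1 walk) too.
#' @return An `mda_scores` object.
#' @name baselines
NULL

#' @rdname baselines
#' @export
user_based_cf <- function(A, SM_mir) {
  SM_mir <- as_similarity_matrix(SM_mir)
  stopifnot(nrow(A) == nrow(SM_mir))
  num <- SM_mir %*% A - diag(SM_mir) * A
  den <- rowSums(abs(SM_mir)) - abs(diag(SM_mir))
  SS <- num / ifelse(den == 0, 1, den)
  SS[den == 0, ] <- 0
  dimnames(SS) <- dimnames(A)
  new_mda_scores(SS, method = "user_cf")
}

#' @rdname baselines
#' @export
item_based_cf <- function(A, SM_dis) {
  SM_dis <- as_similarity_matrix(SM_dis)
  stopifnot(ncol(A) == nrow(SM_dis))
  num <- A %*% SM_dis - A * rep(diag(SM_dis), each = nrow(A))
  den <- colSums(abs(SM_dis)) - abs(diag(SM_dis))
  SS <- sweep(num, 2, ifelse(den == 0, 1, den), "/")
  SS[, den == 0] <- 0
  dimnames(SS) <- dimnames(A)
  new_mda_scores(SS, method = "item_cf")
}

#' @rdname baselines
#' @export
neighbor_based_cf <- function(A, SM_mir, SM_dis, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  SS <- lambda * user_based_cf(A, SM_mir)$SS +
    (1 - lambda) * item_based_cf(A, SM_dis)$SS
  new_mda_scores(SS, method = "neighbor_cf", lambda = lambda)
}

#' @rdname baselines
#' @export
katz_scores <- function(A, SM_mir, SM_dis, katz_beta = 0.01, max_length = 4,
                        include_direct = TRUE) {
  SM_mir <- as_similarity_matrix(SM_mir)
  SM_dis <- as_similarity_matrix(SM_dis)
  stopifnot(katz_beta > 0, max_length >= 2)
  n_m <- nrow(A)
  n_d <- ncol(A)
  H <- rbind(cbind(SM_mir, A), cbind(t(A), SM_dis))
  rho <- max(abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
  if (rho > 0 && katz_beta >= 1 / rho) {
    message("katz_beta = ", katz_beta, " is at or above 1/spectral radius (",
            format(1 / rho, digits = 4), "); truncated series may be unstable")
  }
  S_full <- matrix(0, n_m + n_d, n_m + n_d)
  Hp <- diag(n_m + n_d)
  for (l in seq_len(max_length)) {
    Hp <- Hp %*% H
    if (any(!is.finite(Hp))) {
      stop("non-finite walk counts at length ", l,
           "; use a smaller katz_beta", call. = FALSE)
    }
    if (l >= 2 || include_direct) {
      S_full <- S_full + katz_beta^l * Hp
    }
  }
  SS <- S_full[seq_len(n_m), n_m + seq_len(n_d), drop = FALSE]
  dimnames(SS) <- dimnames(A)
  new_mda_scores(SS, method = "katz", katz_beta = katz_beta,
                 max_length = max_length)
}

#' Baseline scorers in the shared scorer contract
#'
#' Wraps a named baseline as a `(A_train, SM_mir, SM_dis, config)` scorer so
#' it plugs into [loocv()] and [kfold_cv()] exactly like [diffusion_scorer()].
#'
#' @param method One of `"user-cf"`, `"item-cf"`, `"neighbor-cf"`, `"katz"`.
#' @return A scorer function.
#' @examples
#' sc <- baseline_scorer("user-cf")
#' @export
baseline_scorer <- function(method = c("user-cf", "item-cf", "neighbor-cf",
                                       "katz")) {
  method <- match.arg(method)
  switch(
    method,
    "user-cf" = function(A, SM_mir, SM_dis, config = mda_config()) {
      user_based_cf(A, SM_mir)$SS
    },
    "item-cf" = function(A, SM_mir, SM_dis, config = mda_config()) {
      item_based_cf(A, SM_dis)$SS
    },
    "neighbor-cf" = function(A, SM_mir, SM_dis, config = mda_config()) {
      neighbor_based_cf(A, SM_mir, SM_dis, config$lambda_neighbor)$SS
    },
    "katz" = function(A, SM_mir, SM_dis, config = mda_config()) {
      katz_scores(A, SM_mir, SM_dis, config$katz_beta, config$katz_max_length,
                  config$katz_include_direct)$SS
    }
  )
}
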