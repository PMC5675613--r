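#' Build the two similarity-weighted association networks
#'
#' The binary association matrix A (miRNAs x diseases) is weighted once on the
#' disease side and once on the miRNA side:
#' `A_d = A %*% SM_dis` spreads each association over semantically similar
#' diseases, and `A_m = SM_mir %*% A` spreads it over expression-similar
#' miRNAs. With identity similarity matrices both reduce to A exactly.
#'
#' @param A Binary numeric matrix, miRNAs x diseases, with dimnames.
#' @param SM_dis Disease similarity matrix (n_d x n_d) or `mda_similarity`.
#' @param SM_mir miRNA similarity matrix (n_m x n_m) or `mda_similarity`.
#' @return A list with elements `A_d` and `A_m`, both n_m x n_d.
#' @export
build_weighted_networks <- function(A, SM_dis, SM_mir) {
  SM_dis <- as_similarity_matrix(SM_dis)
  SM_mir <- as_similarity_matrix(SM_mir)
  if (ncol(A) != nrow(SM_dis) || nrow(SM_dis) != ncol(SM_dis)) {
    stop("disease similarity must be square with dimension ncol(A)",
         call. = FALSE)
  }
  if (nrow(A) != nrow(SM_mir) || nrow(SM_mir) != ncol(SM_mir)) {
    stop("miRNA similarity must be square with dimension nrow(A)",
         call. = FALSE)
  }
  A_d <- A %*% SM_dis
  A_m <- SM_mir %*% A
  dimnames(A_d) <- dimnames(A)
  dimnames(A_m) <- dimnames(A)
  list(A_d = A_d, A_m = A_m)
}

as_similarity_matrix <- function(x) {
  if (inherits(x, "mda_similarity")) x$S else x
}

#' Column and row diffusion shares of a weighted network
#'
#' `W(i, j) = A_w(i, j) / colsum_j(A_w)` and
#' `M(i, j) = A_w(i, j) / rowsum_i(A_w)`, with the 0/0 convention: a column
#' (row) whose sum is zero yields an all-zero column (row) of shares, never
#' NaN. These shares are the normalisers of the resource and feedback steps.
#'
#' @param A_w Numeric matrix (a weighted association network).
#' @return A list with `W` (column shares) and `M` (row shares), same shape.
#' @export
diffusion_shares <- function(A_w) {
  stopifnot(all(is.finite(A_w)))
  cs <- colSums(A_w)
  rs <- rowSums(A_w)
  W <- sweep(A_w, 2, ifelse(cs == 0, 1, cs), "/")
  W[, cs == 0] <- 0
  M <- sweep(A_w, 1, ifelse(rs == 0, 1, rs), "/")
  M[rs == 0, ] <- 0
  list(W = W, M = M)
}

#' Two-way diffusion scores on the bipartite association network
#'
#' Three steps. Step 1 diffuses the raw associations through each weighted
#' network to produce miRNA-to-miRNA and disease-to-disease resource matrices,
#' combined across the two networks with damping weights `alpha` (miRNA side)
#' and `beta` (disease side). Step 2 feeds the combined resources back through
#' the networks to give miRNA-to-disease and disease-to-miRNA feedback scores,
#' combined with the same weights. Step 3 averages the two feedback matrices
#' (transposing the disease-side one) into the final score matrix SS. The
#' diffusion is exactly these two passes; it is not iterated to convergence.
#'
#' @param A Binary association matrix (miRNAs x diseases), with dimnames.
#' @param nets Weighted networks from [build_weighted_networks()].
#' @param alpha,beta Damping coefficients in \[0, 1\].
#' @return An object of class `mda_scores`: list with `SS` (numeric matrix,
#'   miRNAs x diseases), `alpha`, `beta`.
#' @export
two_way_diffusion <- function(A, nets, alpha = 0.5, beta = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  sh_d <- diffusion_shares(nets$A_d)
  sh_m <- diffusion_shares(nets$A_m)

  # step 1: resource matrices (miRNA x miRNA and disease x disease)
  R1_mir_d <- sh_d$W %*% t(A)
  R1_mir_m <- sh_m$W %*% t(A)
  R1_dis_d <- t(sh_d$M) %*% A
  R1_dis_m <- t(sh_m$M) %*% A
  S1_mir <- alpha * R1_mir_d + (1 - alpha) * R1_mir_m
  S1_dis <- beta * R1_dis_d + (1 - beta) * R1_dis_m
  if (any(!is.finite(S1_mir)) || any(!is.finite(S1_dis))) {
    stop("non-finite values in diffusion step 1", call. = FALSE)
  }

  # step 2: feedback matrices (miRNA x disease and disease x miRNA)
  R2_mir_d <- sh_d$W %*% S1_dis
  R2_mir_m <- sh_m$W %*% S1_dis
  R2_dis_d <- t(sh_d$M) %*% S1_mir
  R2_dis_m <- t(sh_m$M) %*% S1_mir
  S2_mir <- alpha * R2_mir_d + (1 - alpha) * R2_mir_m
  S2_dis <- beta * R2_dis_d + (1 - beta) * R2_dis_m
  if (any(!is.finite(S2_mir)) || any(!is.finite(S2_dis))) {
    stop("non-finite values in diffusion step 2", call. = FALSE)
  }

  # step 3: average the two feedback views
  SS <- (S2_mir + t(S2_dis)) / 2
  dimnames(SS) <- dimnames(A)
  new_mda_scores(SS, alpha = alpha, beta = beta, method = "diffusion")
}

new_mda_scores <- function(SS, ..., method) {
  structure(list(SS = SS, method = method, ...), class = "mda_scores")
}

#' @export
print.mda_scores <- function(x, ...) {
  cat("<mda_scores> method =", x$method, ":", nrow(x$SS), "miRNAs x",
      ncol(x$SS), "diseases\n")
  invisible(x)
}

#' End-to-end prediction from input files
#'
#' Reads the association list, expression profiles and disease DAGs, builds
#' both similarity matrices, and runs the two-way diffusion. The association
#' file defines the miRNA and disease universes (order of first appearance);
#' miRNAs without an expression row and diseases without a DAG are handled by
#' the mean-imputation rules of the similarity builders.
#'
#' @param associations Path to the association file
#'   (see [read_association_table()]).
#' @param expression Path to the expression TSV
#'   (see [read_expression_matrix()]).
#' @param dags Path to the DAG edge-list TSV (see [read_dag_table()]).
#' @param config An [mda_config()].
#' @return An `mda_scores` object with the fitted inputs attached
#'   (`A`, `SM_mir`, `SM_dis`).
#' @export
mda_predict <- function(associations, expression, dags,
                        config = mda_config()) {
  tab <- read_association_table(associations)
  A <- build_association_matrix(tab)
  expr <- read_expression_matrix(expression)
  dag_tab <- read_dag_table(dags)
  sm_mir <- build_mirna_similarity(expr, rownames(A), config)
  sm_dis <- build_disease_similarity(dag_tab, colnames(A),
                                     delta = config$delta)
  scores <- score_dataset(A, sm_mir$S, sm_dis$S, config)
  scores$A <- A
  scores$SM_mir <- sm_mir
  scores$SM_dis <- sm_dis
  scores
}

#' Score an in-memory dataset with the diffusion model
#'
#' The scorer contract shared by the diffusion model and all baselines:
#' association matrix plus the two similarity matrices in, score matrix out.
#'
#' @param A Binary association matrix (miRNAs x diseases).
#' @param SM_mir,SM_dis Similarity matrices (or `mda_similarity` objects).
#' @param config An [mda_config()]; uses `alpha` and `beta`.
#' @return An `mda_scores` object.
#' @export
score_dataset <- function(A, SM_mir, SM_dis, config = mda_config()) {
  nets <- build_weighted_networks(A, SM_dis, SM_mir)
  two_way_diffusion(A, nets, alpha = config$alpha, beta = config$beta)
}

#' Long-format view of a score matrix
#'
#' @param scores An `mda_scores` object or plain score matrix.
#' @param known Optional binary association matrix marking known pairs.
#' @return A tibble (mirna, disease, score, is_known) sorted by descending
#'   score.
#' @export
scores_to_table <- function(scores, known = NULL) {
  SS <- if (inherits(scores, "mda_scores")) scores$SS else scores
  tab <- tibble::tibble(
    mirna = rep(rownames(SS), times = ncol(SS)),
    disease = rep(colnames(SS), each = nrow(SS)),
    score = as.vector(SS)
  )
  if (!is.null(known)) {
    tab$is_known <- as.vector(known) == 1
  }
  dplyr::arrange(tab, dplyr::desc(.data$score))
}
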