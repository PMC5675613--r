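# Independent oracles: literal per-element evaluations of the model's
# defining sums, kept free of the matrix-form implementation they check.

# Two-way diffusion written as explicit scalar sums. share(i,j) over columns
# and rows with the 0/0 -> 0 convention, then the three steps element by
# element.
oracle_diffusion <- function(A, SM_dis, SM_mir, alpha, beta) {
  n_m <- nrow(A)
  n_d <- ncol(A)
  A_d <- matrix(0, n_m, n_d)
  A_m <- matrix(0, n_m, n_d)
  for (i in seq_len(n_m)) {
    for (j in seq_len(n_d)) {
      for (k in seq_len(n_d)) A_d[i, j] <- A_d[i, j] + A[i, k] * SM_dis[k, j]
      for (k in seq_len(n_m)) A_m[i, j] <- A_m[i, j] + SM_mir[i, k] * A[k, j]
    }
  }
  col_share <- function(Aw, i, j) {
    s <- 0
    for (t in seq_len(n_m)) s <- s + Aw[t, j]
    if (s == 0) 0 else Aw[i, j] / s
  }
  row_share <- function(Aw, n, m) {
    s <- 0
    for (t in seq_len(n_d)) s <- s + Aw[n, t]
    if (s == 0) 0 else Aw[n, m] / s
  }
  # step 1: r1(miRNA_i) sums column shares against columns of A;
  # r1(disease_m) sums row shares against rows of A
  r1_mir <- function(Aw) {
    out <- matrix(0, n_m, n_m)
    for (i in seq_len(n_m)) {
      for (j in seq_len(n_d)) {
        w <- col_share(Aw, i, j)
        for (k in seq_len(n_m)) out[i, k] <- out[i, k] + w * A[k, j]
      }
    }
    out
  }
  r1_dis <- function(Aw) {
    out <- matrix(0, n_d, n_d)
    for (m in seq_len(n_d)) {
      for (n in seq_len(n_m)) {
        w <- row_share(Aw, n, m)
        for (l in seq_len(n_d)) out[m, l] <- out[m, l] + w * A[n, l]
      }
    }
    out
  }
  S1_mir <- alpha * r1_mir(A_d) + (1 - alpha) * r1_mir(A_m)
  S1_dis <- beta * r1_dis(A_d) + (1 - beta) * r1_dis(A_m)
  # step 2: feedback through the same shares against the step-1 resources
  r2_mir <- function(Aw) {
    out <- matrix(0, n_m, n_d)
    for (i in seq_len(n_m)) {
      for (j in seq_len(n_d)) {
        w <- col_share(Aw, i, j)
        for (l in seq_len(n_d)) out[i, l] <- out[i, l] + w * S1_dis[j, l]
      }
    }
    out
  }
  r2_dis <- function(Aw) {
    out <- matrix(0, n_d, n_m)
    for (m in seq_len(n_d)) {
      for (n in seq_len(n_m)) {
        w <- row_share(Aw, n, m)
        for (k in seq_len(n_m)) out[m, k] <- out[m, k] + w * S1_mir[n, k]
      }
    }
    out
  }
  S2_mir <- alpha * r2_mir(A_d) + (1 - alpha) * r2_mir(A_m)
  S2_dis <- beta * r2_dis(A_d) + (1 - beta) * r2_dis(A_m)
  (S2_mir + t(S2_dis)) / 2
}

# Semantic contribution by exhaustive enumeration of descending paths from a
# term to the disease term: contribution = delta ^ (shortest path length).
oracle_contribution <- function(dag, delta) {
  children_of <- split(dag$edges[, "child"], dag$edges[, "parent"])
  min_len <- function(t) {
    if (t == dag$disease_id) return(0L)
    kids <- children_of[[t]]
    if (is.null(kids)) return(NA_integer_)
    lens <- vapply(kids, min_len, 0L)
    if (all(is.na(lens))) NA_integer_ else 1L + min(lens, na.rm = TRUE)
  }
  v <- vapply(dag$terms, min_len, 0L)
  stats::setNames(delta^v, dag$terms)
}

oracle_semantic_similarity <- function(dag_i, dag_j, delta) {
  ci <- oracle_contribution(dag_i, delta)
  cj <- oracle_contribution(dag_j, delta)
  shared <- intersect(names(ci), names(cj))
  if (length(shared) == 0) return(0)
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

# AUC as explicit pairwise concordance over all positive x negative pairs.
oracle_concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Weighted walk counts on the heterogeneous network by per-element dynamic
# programming: paths[l][i, j] = sum_k paths[l-1][i, k] * H[k, j].
oracle_katz <- function(A, SM_mir, SM_dis, katz_beta, max_length,
                        include_direct) {
  n_m <- nrow(A)
  n_d <- ncol(A)
  H <- rbind(cbind(SM_mir, A), cbind(t(A), SM_dis))
  n <- nrow(H)
  paths <- diag(n)
  total <- matrix(0, n, n)
  for (l in seq_len(max_length)) {
    nxt <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + paths[i, k] * H[k, j]
        nxt[i, j] <- acc
      }
    }
    paths <- nxt
    if (l >= 2 || include_direct) total <- total + katz_beta^l * paths
  }
  total[seq_len(n_m), n_m + seq_len(n_d), drop = FALSE]
}

# Collaborative filtering as double loops over the defining sums.
oracle_user_cf <- function(A, SM_mir) {
  n_m <- nrow(A)
  n_d <- ncol(A)
  out <- matrix(0, n_m, n_d)
  for (i in seq_len(n_m)) {
    ks <- setdiff(seq_len(n_m), i)
    den <- sum(abs(SM_mir[i, ks]))
    for (j in seq_len(n_d)) {
      num <- sum(SM_mir[i, ks] * A[ks, j])
      out[i, j] <- if (den == 0) 0 else num / den
    }
  }
  out
}

oracle_item_cf <- function(A, SM_dis) {
  n_m <- nrow(A)
  n_d <- ncol(A)
  out <- matrix(0, n_m, n_d)
  for (j in seq_len(n_d)) {
    ls <- setdiff(seq_len(n_d), j)
    den <- sum(abs(SM_dis[ls, j]))
    for (i in seq_len(n_m)) {
      num <- sum(A[i, ls] * SM_dis[ls, j])
      out[i, j] <- if (den == 0) 0 else num / den
    }
  }
  out
}

# ---- random instance generators -------------------------------------------

rand_similarity <- function(n, allow_negative = TRUE) {
  S <- matrix(stats::runif(n * n, if (allow_negative) -0.3 else 0, 1), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

rand_instance <- function(n_m, n_d, density = 0.3, allow_negative = FALSE) {
  A <- matrix(as.numeric(stats::runif(n_m * n_d) < density), n_m, n_d,
              dimnames = list(sprintf("m%02d", seq_len(n_m)),
                              sprintf("d%02d", seq_len(n_d))))
  list(A = A,
       SM_mir = rand_similarity(n_m, allow_negative),
       SM_dis = rand_similarity(n_d, allow_negative))
}

# Random DAG with every term reaching the disease term: term k >= 2 gets at
# least one child among terms 1..k-1 (term 1 is the disease's own term), so
# edges always point from lower to higher index and the graph is acyclic.
rand_dag <- function(disease_id, pool, n_terms) {
  anc <- sample(pool, n_terms - 1)
  terms <- c(disease_id, anc)
  child <- character()
  parent <- character()
  for (k in seq_along(terms)[-1]) {
    kids <- sample.int(k - 1, size = sample.int(min(2, k - 1), 1))
    child <- c(child, terms[kids])
    parent <- c(parent, rep(terms[[k]], length(kids)))
  }
  make_disease_dag(disease_id, child, parent)
}
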