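#' Construct a disease term DAG
#'
#' A disease is represented by its own MeSH-style term plus all ancestor
#' terms, connected by child-to-parent edges. The disease's own term is the
#' sink of contribution flow: it has no children inside the DAG, and every
#' other term must reach it by descending edges.
#'
#' @param disease_id The disease id; its term must appear among the edge
#'   children (or be the only term for a root-only disease).
#' @param child,parent Character vectors of equal length: one child-to-parent
#'   edge per position.
#' @return An object of class `mda_dag` with elements `disease_id`, `terms`,
#'   and `edges` (two-column character matrix).
#' @export
make_disease_dag <- function(disease_id, child = character(), parent = character()) {
  stopifnot(length(child) == length(parent))
  edges <- cbind(child = as.character(child), parent = as.character(parent))
  terms <- unique(c(disease_id, child, parent))
  if (disease_id %in% edges[, "parent"]) {
    stop("disease term '", disease_id, "' has children inside its own DAG",
         call. = FALSE)
  }
  structure(list(disease_id = disease_id, terms = terms, edges = edges),
            class = "mda_dag")
}

#' Semantic contribution of each DAG term to its disease
#'
#' The disease's own term contributes 1. Every ancestor term t contributes
#' `max over children t' of delta * contribution(t')`, which equals
#' `delta ^ (minimum number of descending edges from t to the disease term)`.
#' Computed by breadth-first distances from the disease term along reversed
#' (parent-of) edges, which is the dynamic-programming evaluation of the
#' recursion in reverse topological order.
#'
#' @param dag An `mda_dag` (see [make_disease_dag()]).
#' @param delta Decay factor in (0, 1).
#' @return Named numeric vector: contribution in (0, 1\] for every DAG term.
#' @examples
#' dag <- make_disease_dag("d", child = c("d", "p"), parent = c("p", "g"))
#' semantic_contribution(dag, 0.5)
#' @export
semantic_contribution <- function(dag, delta) {
  stopifnot(inherits(dag, "mda_dag"), delta > 0, delta < 1)
  assert_acyclic(dag)
  terms <- dag$terms
  # parents_of[[t]]: terms one level above t (t is their child)
  parents_of <- split(dag$edges[, "parent"], dag$edges[, "child"])
  dist <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  dist[dag$disease_id] <- 0L
  frontier <- dag$disease_id
  level <- 0L
  while (length(frontier) > 0) {
    level <- level + 1L
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- level
    frontier <- nxt
  }
  if (anyNA(dist)) {
    stop("malformed DAG for '", dag$disease_id, "': term(s) ",
         paste(names(dist)[is.na(dist)], collapse = ", "),
         " cannot reach the disease term by descending edges", call. = FALSE)
  }
  delta^dist
}

assert_acyclic <- function(dag) {
  edges <- dag$edges
  if (nrow(edges) == 0) return(invisible(TRUE))
  terms <- dag$terms
  indeg <- stats::setNames(integer(length(terms)), terms)
  tab <- table(edges[, "parent"])
  indeg[names(tab)] <- as.integer(tab)
  children_of <- split(edges[, "parent"], edges[, "child"])
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue) > 0) {
    t <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (p in children_of[[t]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(terms)) {
    stop("cycle detected in DAG for '", dag$disease_id, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Semantic similarity between two diseases
#'
#' The shared-term contributions, summed from both sides, divided by the total
#' contribution of both DAGs. The term set of each disease includes its own
#' term (contribution 1) as well as all ancestors, so the self-similarity of
#' any disease is exactly 1. Disjoint term sets give 0.
#'
#' @param c_i,c_j Named contribution vectors from [semantic_contribution()],
#'   computed with the same `delta`.
#' @return A number in \[0, 1\].
#' @export
semantic_similarity <- function(c_i, c_j) {
  shared <- intersect(names(c_i), names(c_j))
  if (length(shared) == 0) return(0)
  sum(c_i[shared] + c_j[shared]) / (sum(c_i) + sum(c_j))
}

#' Build the disease semantic similarity matrix
#'
#' Pairwise semantic similarity for all diseases of the universe that have a
#' DAG. Diseases without a DAG get, against every other disease, the
#' arithmetic mean of all computable off-diagonal pair similarities (the same
#' imputation rule used for missing expression profiles); those entries are
#' flagged. The diagonal is always 1.
#'
#' @param dags Either a tibble with columns `disease`, `child`, `parent` (as
#'   returned by [read_dag_table()]) or a list of `mda_dag` objects.
#' @param universe Character vector of disease ids defining matrix order.
#' @param delta Decay factor in (0, 1); default from [mda_config()].
#' @return An `mda_similarity` list: `S`, `imputed`, `mean_similarity`.
#' @export
build_disease_similarity <- function(dags, universe, delta = 0.5) {
  stopifnot(length(universe) > 0, !anyDuplicated(universe))
  if (is.data.frame(dags)) {
    dags <- dag_table_to_list(dags)
  }
  ids <- vapply(dags, function(d) d$disease_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate DAG for disease(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(dags) <- ids
  have <- universe %in% ids
  contribs <- purrr::map(dags[universe[have]], semantic_contribution,
                         delta = delta)

  n <- length(universe)
  S <- matrix(1, n, n, dimnames = list(universe, universe))
  imputed <- matrix(FALSE, n, n, dimnames = list(universe, universe))
  idx <- which(have)
  if (length(idx) >= 2) {
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        v <- semantic_similarity(contribs[[a]], contribs[[b]])
        S[idx[a], idx[b]] <- v
        S[idx[b], idx[a]] <- v
      }
    }
  }
  mean_sim <- NA_real_
  if (any(!have)) {
    if (length(idx) < 2) {
      stop("no computable disease pair: imputation mean undefined",
           call. = FALSE)
    }
    block <- S[idx, idx]
    mean_sim <- mean(block[upper.tri(block)])
    miss <- which(!have)
    S[miss, ] <- mean_sim
    S[, miss] <- mean_sim
    imputed[miss, ] <- TRUE
    imputed[, miss] <- TRUE
    diag(S) <- 1
    diag(imputed) <- FALSE
  }
  structure(
    list(S = S, imputed = imputed, mean_similarity = mean_sim,
         kind = "disease_semantic"),
    class = "mda_similarity"
  )
}

dag_table_to_list <- function(tab) {
  stopifnot(all(c("disease", "child", "parent") %in% names(tab)))
  purrr::map(split(tab, tab$disease), function(d) {
    make_disease_dag(d$disease[[1]], d$child, d$parent)
  })
}
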