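#' Specification of a synthetic miRNA-disease benchmark
#'
#' Describes a planted-structure dataset: miRNAs fall into expression
#' clusters (a Gaussian template per cluster plus per-miRNA noise), diseases
#' sit on a rooted tree of MeSH-style terms, and each miRNA cluster is wired
#' to a contiguous block of tree-adjacent diseases. This is the regime the
#' diffusion model assumes - expression-similar miRNAs share semantically
#' similar diseases - so recovery of held-out links is a meaningful check.
#'
#' @param n_mirnas,n_diseases,n_tissues Problem dimensions.
#' @param n_clusters Number of miRNA clusters (= disease blocks).
#' @param dag_branching,dag_depth Shape of the rooted disease term tree; it
#'   must have at least `n_diseases` non-root nodes.
#' @param dag_extra_edges Number of additional cross edges (deeper term to a
#'   shallower non-ancestor term), exercising the multi-path decay rule.
#' @param assoc_per_cluster Diseases linked to each miRNA, drawn from its
#'   cluster's disease block (block size must be >= this).
#' @param noise_assoc_fraction Fraction of associations replaced by uniform
#'   random pairs.
#' @param expression_noise_sd Standard deviation of per-miRNA expression noise
#'   around the cluster template (templates are standard normal per tissue).
#' @param missing_profile_fraction Fraction of miRNAs whose expression row is
#'   deleted (their similarities are mean-imputed downstream).
#' @param seed Seed controlling all randomness.
#' @return An object of class `mda_synthetic_spec`.
#' @export
synthetic_spec <- function(n_mirnas = 60, n_diseases = 30, n_tissues = 40,
                           n_clusters = 6, dag_branching = 2, dag_depth = 4,
                           dag_extra_edges = 0, assoc_per_cluster = 3,
                           noise_assoc_fraction = 0.1,
                           expression_noise_sd = 0.5,
                           missing_profile_fraction = 0.1, seed = 42) {
  spec <- list(
    n_mirnas = as.integer(n_mirnas), n_diseases = as.integer(n_diseases),
    n_tissues = as.integer(n_tissues), n_clusters = as.integer(n_clusters),
    dag_branching = as.integer(dag_branching),
    dag_depth = as.integer(dag_depth),
    dag_extra_edges = as.integer(dag_extra_edges),
    assoc_per_cluster = as.integer(assoc_per_cluster),
    noise_assoc_fraction = noise_assoc_fraction,
    expression_noise_sd = expression_noise_sd,
    missing_profile_fraction = missing_profile_fraction,
    seed = as.integer(seed)
  )
  stopifnot(
    spec$n_mirnas >= 1, spec$n_diseases >= 1, spec$n_tissues >= 2,
    spec$n_clusters >= 1, spec$n_clusters <= spec$n_mirnas,
    spec$dag_branching >= 1, spec$dag_depth >= 1,
    spec$assoc_per_cluster >= 1,
    noise_assoc_fraction >= 0, noise_assoc_fraction < 1,
    expression_noise_sd >= 0,
    missing_profile_fraction >= 0, missing_profile_fraction < 1
  )
  n_tree <- sum(spec$dag_branching^seq_len(spec$dag_depth))
  if (n_tree < spec$n_diseases) {
    stop("term tree has ", n_tree, " non-root nodes but ", spec$n_diseases,
         " diseases requested; increase dag_branching or dag_depth",
         call. = FALSE)
  }
  block <- min(table(rep(seq_len(spec$n_clusters),
                         length.out = spec$n_diseases)))
  if (block < spec$assoc_per_cluster) {
    stop("smallest disease block (", block, ") is below assoc_per_cluster (",
         spec$assoc_per_cluster, ")", call. = FALSE)
  }
  structure(spec, class = "mda_synthetic_spec")
}

#' Generate a synthetic miRNA-disease dataset
#'
#' See [synthetic_spec()] for the construction. All randomness derives from
#' `spec$seed`; the same spec always yields an identical dataset.
#'
#' @param spec An [synthetic_spec()].
#' @return An object of class `mda_synthetic`: `expression` (matrix, missing
#'   miRNAs' rows deleted), `dags` (tibble disease/child/parent),
#'   `associations` (tibble mirna/disease/is_noise), `truth` (list with
#'   `mirna_cluster`, `disease_block`, `missing_mirnas`), and `spec`.
#' @examples
#' d <- generate_synthetic(synthetic_spec(n_mirnas = 12, n_diseases = 8,
#'                                        n_clusters = 2))
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "mda_synthetic_spec"))
  withr::with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  mirnas <- sprintf("mir-%03d", seq_len(spec$n_mirnas))
  diseases <- sprintf("D%03d", seq_len(spec$n_diseases))
  tissues <- sprintf("tissue%02d", seq_len(spec$n_tissues))

  # rooted term tree in depth-first order, so contiguous disease blocks are
  # anchored in neighbouring subtrees
  tree <- build_term_tree(spec$dag_branching, spec$dag_depth)
  node_of <- tree$dfs_nodes[seq_len(spec$n_diseases)]
  dag_rows <- purrr::map(seq_len(spec$n_diseases), function(k) {
    chain <- ancestor_chain(node_of[[k]], tree$parent)
    tibble::tibble(
      disease = diseases[[k]],
      child = c(diseases[[k]], chain[-length(chain)]),
      parent = chain
    )
  })
  dags <- dplyr::bind_rows(dag_rows)
  if (spec$dag_extra_edges > 0) {
    dags <- dplyr::bind_rows(dags, cross_edges(spec, diseases, node_of, tree))
  }

  # clustered expression: template per cluster + per-miRNA Gaussian noise
  cluster <- sort(rep(seq_len(spec$n_clusters), length.out = spec$n_mirnas))
  templates <- matrix(stats::rnorm(spec$n_clusters * spec$n_tissues),
                      spec$n_clusters, spec$n_tissues)
  expression <- templates[cluster, , drop = FALSE] +
    matrix(stats::rnorm(spec$n_mirnas * spec$n_tissues,
                        sd = spec$expression_noise_sd),
           spec$n_mirnas, spec$n_tissues)
  dimnames(expression) <- list(mirnas, tissues)

  # planted associations: each miRNA links inside its cluster's disease block
  block_id <- sort(rep(seq_len(spec$n_clusters), length.out = spec$n_diseases))
  assoc <- purrr::map_dfr(seq_len(spec$n_mirnas), function(i) {
    pool <- which(block_id == cluster[[i]])
    picked <- pool[sample.int(length(pool), spec$assoc_per_cluster)]
    tibble::tibble(mirna = mirnas[[i]], disease = diseases[picked],
                   is_noise = FALSE)
  })

  # noise: replace a fraction with uniform random pairs (count never grows)
  n_noise <- round(spec$noise_assoc_fraction * nrow(assoc))
  if (n_noise > 0) {
    rows <- sample.int(nrow(assoc), n_noise)
    assoc$mirna[rows] <- mirnas[sample.int(spec$n_mirnas, n_noise,
                                           replace = TRUE)]
    assoc$disease[rows] <- diseases[sample.int(spec$n_diseases, n_noise,
                                               replace = TRUE)]
    assoc$is_noise[rows] <- TRUE
  }
  assoc <- dplyr::distinct(assoc, .data$mirna, .data$disease,
                           .keep_all = TRUE)

  missing <- character()
  n_missing <- round(spec$missing_profile_fraction * spec$n_mirnas)
  if (n_missing > 0) {
    missing <- sort(mirnas[sample.int(spec$n_mirnas, n_missing)])
    expression <- expression[setdiff(mirnas, missing), , drop = FALSE]
  }

  structure(
    list(
      expression = expression,
      dags = dags,
      associations = assoc,
      truth = list(
        mirna_cluster = tibble::tibble(mirna = mirnas, cluster = cluster),
        disease_block = tibble::tibble(disease = diseases, block = block_id,
                                       term_node = node_of),
        missing_mirnas = missing
      ),
      spec = spec
    ),
    class = "mda_synthetic"
  )
}

build_term_tree <- function(branching, depth) {
  parent <- c(root = NA_character_)
  names(parent) <- "root"
  dfs <- character()
  walk <- function(node, level) {
    if (level == depth) return(invisible(NULL))
    for (b in seq_len(branching)) {
      child <- paste0(node, ".", b)
      parent[[child]] <<- node
      dfs <<- c(dfs, child)
      walk(child, level + 1)
    }
  }
  walk("root", 0)
  list(parent = parent, dfs_nodes = dfs)
}

ancestor_chain <- function(node, parent) {
  chain <- node
  while (!is.na(parent[[chain[length(chain)]]])) {
    chain <- c(chain, parent[[chain[length(chain)]]])
  }
  chain
}

cross_edges <- function(spec, diseases, node_of, tree) {
  all_nodes <- c("root", tree$dfs_nodes)
  level <- nchar(gsub("[^.]", "", all_nodes))
  extra <- purrr::map_dfr(seq_len(spec$dag_extra_edges), function(e) {
    k <- sample.int(spec$n_diseases, 1)
    anc <- ancestor_chain(node_of[[k]], tree$parent)
    deep <- anc[[1]]
    shallower <- all_nodes[level < level[match(deep, all_nodes)] &
                             !all_nodes %in% anc]
    if (length(shallower) == 0) return(NULL)
    tibble::tibble(disease = diseases[[k]], child = deep,
                   parent = shallower[[sample.int(length(shallower), 1)]])
  })
  extra
}

#' Write a synthetic dataset's input files
#'
#' Writes `associations.tsv`, `expression.tsv`, `dags.tsv` and `truth.tsv`
#' into a directory, in exactly the formats the package readers consume.
#'
#' @param dataset An `mda_synthetic` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mda_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_table(dataset$associations, file.path(dir, "associations.tsv"))
  write_expression_matrix(dataset$expression, file.path(dir, "expression.tsv"))
  write_dag_table(dataset$dags, file.path(dir, "dags.tsv"))
  truth <- dplyr::left_join(dataset$associations,
                            dataset$truth$mirna_cluster, by = "mirna")
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Assemble an evaluation-ready dataset from a synthetic object
#'
#' Builds the association matrix and both similarity matrices from the
#' generated inputs, giving the [mda_dataset()] consumed by [loocv()] and
#' [kfold_cv()].
#'
#' @param dataset An `mda_synthetic` object.
#' @param config An [mda_config()].
#' @return An `mda_dataset`.
#' @export
as_mda_dataset <- function(dataset, config = mda_config()) {
  stopifnot(inherits(dataset, "mda_synthetic"))
  A <- build_association_matrix(dataset$associations)
  sm_mir <- build_mirna_similarity(dataset$expression, rownames(A), config)
  sm_dis <- build_disease_similarity(dataset$dags, colnames(A),
                                     delta = config$delta)
  mda_dataset(A, sm_mir$S, sm_dis$S)
}
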