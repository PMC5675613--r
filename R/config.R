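#' Run configuration for mirdiff analyses
#'
#' Collects every tunable parameter of the prediction pipeline in one
#' validated list. All downstream functions that need a parameter accept a
#' config object so that a whole run is reproducible from a single value.
#'
#' @param alpha Damping coefficient in \[0, 1\] balancing the
#'   disease-similarity-weighted network against the miRNA-similarity-weighted
#'   network on the miRNA side of the diffusion. Default 0.5.
#' @param beta Same balance on the disease side. Default 0.5.
#' @param delta Semantic contribution decay factor in (0, 1) applied per
#'   ancestor level when scoring disease term hierarchies. Default 0.5.
#' @param clip_negative_similarity If `TRUE`, negative Pearson expression
#'   similarities are replaced by 0 before the diffusion. Default `FALSE`
#'   (correlations are used as computed).
#' @param treat_constant_as_missing If `TRUE`, a zero-variance expression
#'   profile is treated as an absent profile (mean-imputation path) instead of
#'   raising an error. Default `FALSE`.
#' @param lambda_neighbor Weight in \[0, 1\] of the user-based score in the
#'   neighbor-based collaborative-filtering baseline. Default 0.5.
#' @param katz_beta Walk-damping factor (> 0) of the Katz baseline.
#'   Default 0.01.
#' @param katz_max_length Longest walk length counted by the Katz baseline
#'   (integer >= 2). Default 4.
#' @param katz_include_direct If `TRUE` the length-1 walk (the direct
#'   miRNA-disease edge) contributes `katz_beta * A`. Default `TRUE`.
#' @param seed Integer seed for every stochastic step (cross-validation
#'   shuffles, synthetic data). Default 42.
#' @param cv_folds Number of cross-validation folds. Default 5.
#' @param cv_repetitions Number of times the k-fold split is redrawn.
#'   Default 20.
#'
#' @return An object of class `mda_config` (a named list).
#' @examples
#' cfg <- mda_config(alpha = 0.7)
#' cfg$alpha
#' @export
mda_config <- function(alpha = 0.5,
                       beta = 0.5,
                       delta = 0.5,
                       clip_negative_similarity = FALSE,
                       treat_constant_as_missing = FALSE,
                       lambda_neighbor = 0.5,
                       katz_beta = 0.01,
                       katz_max_length = 4L,
                       katz_include_direct = TRUE,
                       seed = 42L,
                       cv_folds = 5L,
                       cv_repetitions = 20L) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
    is.numeric(beta), length(beta) == 1, beta >= 0, beta <= 1,
    is.numeric(delta), length(delta) == 1, delta > 0, delta < 1,
    is.logical(clip_negative_similarity), length(clip_negative_similarity) == 1,
    is.logical(treat_constant_as_missing),
    is.numeric(lambda_neighbor), lambda_neighbor >= 0, lambda_neighbor <= 1,
    is.numeric(katz_beta), katz_beta > 0,
    is.numeric(katz_max_length), katz_max_length >= 2,
    is.logical(katz_include_direct),
    is.numeric(seed), length(seed) == 1,
    is.numeric(cv_folds), cv_folds >= 2,
    is.numeric(cv_repetitions), cv_repetitions >= 1
  )
  structure(
    list(
      alpha = alpha,
      beta = beta,
      delta = delta,
      clip_negative_similarity = clip_negative_similarity,
      treat_constant_as_missing = treat_constant_as_missing,
      lambda_neighbor = lambda_neighbor,
      katz_beta = katz_beta,
      katz_max_length = as.integer(katz_max_length),
      katz_include_direct = katz_include_direct,
      seed = as.integer(seed),
      cv_folds = as.integer(cv_folds),
      cv_repetitions = as.integer(cv_repetitions)
    ),
    class = "mda_config"
  )
}

#' Read a run configuration from a flat key-value file
#'
#' The file holds one `key = value` (or `key: value` / tab-separated) pair per
#' line, keys named exactly as the arguments of [mda_config()]. Lines starting
#' with `#` are comments. Keys absent from the file keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return An `mda_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*[=:\t]\\s*")
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad)) {
    stop("malformed config line: ", lines[which(bad)[1]], call. = FALSE)
  }
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- names(formals(mda_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  logical_keys <- c("clip_negative_similarity", "treat_constant_as_missing",
                    "katz_include_direct")
  args <- purrr::imap(args, function(v, k) {
    if (k %in% logical_keys) as.logical(v) else as.numeric(v)
  })
  do.call(mda_config, args)
}

#' @export
print.mda_config <- function(x, ...) {
  cat("<mda_config>\n")
  for (k in names(x)) cat("  ", k, " = ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}
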