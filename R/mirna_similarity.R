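#' Pearson correlation between two expression profiles
#'
#' The centred Pearson correlation coefficient, used as the expression
#' similarity between two miRNAs profiled across the same tissues.
#'
#' @param x,y Numeric vectors of equal length (>= 2), each with nonzero
#'   variance.
#' @return A number in \[-1, 1\].
#' @examples
#' pearson_similarity(c(1, 2, 3), c(3, 2, 1))
#' @export
pearson_similarity <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2) stop("profiles need length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a zero-variance profile", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Build the miRNA expression similarity matrix
#'
#' Computes pairwise Pearson correlations of expression profiles for every
#' miRNA pair in the universe. For pairs where at least one miRNA lacks a
#' profile, the similarity is imputed as the arithmetic mean of all computable
#' off-diagonal pair similarities (one shared value), and the entry is flagged
#' in the `imputed` mask. The diagonal is always 1 and never flagged.
#'
#' @param expr Numeric matrix, miRNAs x tissues, rownames = miRNA ids. miRNAs
#'   of `universe` absent from its rows are treated as lacking a profile.
#' @param universe Character vector of miRNA ids defining the matrix order
#'   (typically the rownames of the association matrix).
#' @param config An [mda_config()]; uses `treat_constant_as_missing` and
#'   `clip_negative_similarity`.
#' @return A list of class `mda_similarity` with elements `S` (symmetric
#'   numeric matrix with unit diagonal), `imputed` (logical mask of the same
#'   shape), and `mean_similarity` (the shared imputation value, `NA` if
#'   nothing was imputed).
#' @examples
#' expr <- rbind(m1 = c(1, 2, 3), m2 = c(2, 4, 5))
#' build_mirna_similarity(expr, c("m1", "m2", "m3"))
#' @export
build_mirna_similarity <- function(expr, universe, config = mda_config()) {
  stopifnot(length(universe) > 0, !anyDuplicated(universe))
  available <- universe %in% rownames(expr)
  if (any(available)) {
    prof <- expr[universe[available], , drop = FALSE]
    vars <- apply(prof, 1, stats::sd)
    if (any(vars == 0)) {
      flat <- rownames(prof)[vars == 0]
      if (config$treat_constant_as_missing) {
        available[match(flat, universe)] <- FALSE
      } else {
        stop("zero-variance expression profile for miRNA(s): ",
             paste(flat, collapse = ", "), call. = FALSE)
      }
    }
  }
  n <- length(universe)
  S <- matrix(1, n, n, dimnames = list(universe, universe))
  imputed <- matrix(FALSE, n, n, dimnames = list(universe, universe))
  avail_idx <- which(available)
  mean_sim <- NA_real_

  if (length(avail_idx) >= 2) {
    # cor() on the transposed profile block gives all computable pairs at once
    C <- stats::cor(t(expr[universe[avail_idx], , drop = FALSE]))
    S[avail_idx, avail_idx] <- C
    mean_sim <- mean(C[upper.tri(C)])
  }
  if (any(!available)) {
    if (length(avail_idx) < 2) {
      stop("no computable miRNA pair: imputation mean undefined", call. = FALSE)
    }
    miss_idx <- which(!available)
    S[miss_idx, ] <- mean_sim
    S[, miss_idx] <- mean_sim
    imputed[miss_idx, ] <- TRUE
    imputed[, miss_idx] <- TRUE
    diag(S) <- 1
    diag(imputed) <- FALSE
  }
  if (config$clip_negative_similarity) S[S < 0] <- 0
  structure(
    list(S = S, imputed = imputed, mean_similarity = mean_sim,
         kind = "mirna_expression"),
    class = "mda_similarity"
  )
}

#' @export
print.mda_similarity <- function(x, ...) {
  cat("<mda_similarity> (", x$kind, "): ", nrow(x$S), " x ", ncol(x$S),
      ", ", sum(x$imputed[upper.tri(x$imputed)]), " imputed pair(s)\n",
      sep = "")
  invisible(x)
}

#' Write a similarity matrix (and its imputation mask) to TSV
#'
#' @param sim An `mda_similarity` object.
#' @param path Output path for the square similarity matrix; the imputation
#'   mask goes to `paste0(path, ".mask.tsv")` as 0/1 entries.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  write_score_matrix(sim$S, path)
  write_score_matrix(sim$imputed + 0, paste0(path, ".mask.tsv"))
  invisible(path)
}
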