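#' Center Cq values by sample
#'
#' Subtracts each sample's across-gene mean from its column, removing
#' sample-specific loading (RNA input / pipetting) offsets. Cq is already a
#' log-scale measure of expression, so this centering is the log-ratio
#' pre-step of the model-based stability analysis. Column sums of the
#' result are zero by construction.
#'
#' @param m Cq matrix (>= 3 genes, complete).
#' @return centered matrix, same dimnames.
#' @export
center_by_sample <- function(m) {
  m <- as_cq_matrix(m)
  if (anyNA(m)) stop("centering requires a complete Cq matrix")
  sweep(m, 2L, colMeans(m), "-")
}

#' Model-based (NormFinder-style) stability, ungrouped
#'
#' Assumes Cq of gene j in sample i decomposes as gene level + sample
#' loading + noise with gene-specific variance sigma_j^2. After centering by
#' sample, the per-gene variance s2_j of the centered values is a biased
#' estimate of sigma_j^2: centering with k genes mixes in the other genes'
#' variances. The method-of-moments correction used here is
#' `sigma2_hat_j = max(0, (s2_j - mean(s2)/(k-1)) * k/(k-2))`,
#' which follows from the covariance structure induced by subtracting the
#' k-gene mean. Stability is `sqrt(sigma2_hat)`; lower is more stable and 0
#' is the best achievable score (negative moment estimates clamp to zero).
#'
#' @param m Cq matrix with k >= 3 genes and >= 3 samples.
#' @return object of class `normfinder_result`: data.frame `ranking` with
#'   `gene`, `stability`, `sigma2`, `rank`; `grouped = FALSE`.
#' @export
normfinder_ungrouped <- function(m) {
  m <- as_cq_matrix(m)
  k <- nrow(m)
  if (k < 3L) stop("model-based stability requires >= 3 genes (k/(k-2) correction)")
  if (ncol(m) < 3L) stop("need >= 3 samples")
  z <- center_by_sample(m)
  s2 <- apply(z, 1L, stats::var)
  m_bar <- mean(s2)
  sigma2 <- pmax(0, (s2 - m_bar / (k - 1)) * k / (k - 2))
  ranking <- data.frame(gene = rownames(m), stability = sqrt(sigma2),
                        sigma2 = sigma2,
                        rank = rank_from_stability(sqrt(sigma2)),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ranking = ranking, grouped = FALSE), class = "normfinder_result")
}

#' Model-based (NormFinder-style) stability with sample groups
#'
#' With experimental groups (conditions) the model adds a gene-by-group
#' deviation d_gj: a candidate systematically shifted in one condition is a
#' poor reference even if its within-group noise is small. Per gene and
#' group, d_gj is the group mean of the sample-centered values minus the
#' gene's average over group means; within-group variances sigma2_gj are
#' estimated per group with the same k-gene centering correction as the
#' ungrouped analysis. The variance of the true deviations, gamma2, is
#' estimated by moments (observed variance of d minus its sampling noise,
#' clamped at 0) and each d_gj is shrunk toward zero by the empirical-Bayes
#' factor `gamma2 / (gamma2 + sigma2_gj/n_g)`. The stability score is the
#' mean over groups of `|d_shrunk| + sqrt(sigma2_gj/n_g)`, combining
#' systematic deviation and the uncertainty of the gene's group means.
#'
#' @param m Cq matrix (k >= 3 genes, complete).
#' @param groups group label per sample: a named character vector, a factor
#'   in sample order, or an annotation data.frame with columns `sample` and
#'   `group`. At least two groups, each with >= 3 samples.
#' @return object of class `normfinder_result`: `ranking` (`gene`,
#'   `stability`, `rank`), matrices `d` and `d_shrunk` (genes x groups),
#'   `sigma2` (genes x groups), `gamma2`, `n_per_group`, `grouped = TRUE`.
#' @export
normfinder_grouped <- function(m, groups) {
  m <- as_cq_matrix(m)
  k <- nrow(m)
  if (k < 3L) stop("model-based stability requires >= 3 genes")
  groups <- resolve_groups(groups, colnames(m))
  glev <- unique(groups)
  n_g <- table(factor(groups, glev))
  small <- names(n_g)[n_g < 3L]
  if (length(glev) < 2L) stop("grouped analysis requires >= 2 groups")
  if (length(small)) {
    stop("group(s) with fewer than 3 samples: ", paste(small, collapse = ", "))
  }
  z <- center_by_sample(m)
  G <- length(glev)
  zbar <- sapply(glev, function(g) rowMeans(z[, groups == g, drop = FALSE]))
  d <- zbar - rowMeans(zbar)                       # genes x groups deviations
  s2 <- sapply(glev, function(g) {                 # within-group residual var
    zg <- z[, groups == g, drop = FALSE]
    apply(zg, 1L, stats::var)
  })
  # per-group k-gene centering correction, as in the ungrouped estimator
  sigma2 <- sapply(seq_len(G), function(gi) {
    pmax(0, (s2[, gi] - mean(s2[, gi]) / (k - 1)) * k / (k - 2))
  })
  dimnames(sigma2) <- list(rownames(m), glev)
  noise <- sweep(sigma2, 2L, as.numeric(n_g), "/") # var of each group mean
  gamma2 <- max(0, stats::var(as.vector(d)) - mean(noise))
  # gamma2 = 0 shrinks every deviation fully to zero (0/0 guarded)
  d_shrunk <- if (gamma2 == 0) d * 0 else d * gamma2 / (gamma2 + noise)
  stability <- rowMeans(abs(d_shrunk) + sqrt(noise))
  ranking <- data.frame(gene = rownames(m), stability = stability,
                        rank = rank_from_stability(stability),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ranking = ranking, d = d, d_shrunk = d_shrunk,
                 sigma2 = sigma2, gamma2 = gamma2,
                 n_per_group = stats::setNames(as.numeric(n_g), glev),
                 grouped = TRUE),
            class = "normfinder_result")
}

#' Model-based stability (dispatcher)
#'
#' Runs the grouped analysis when group labels are supplied, otherwise the
#' ungrouped one.
#'
#' @param m Cq matrix.
#' @param groups optional group labels (see [normfinder_grouped()]).
#' @return a `normfinder_result`.
#' @export
normfinder <- function(m, groups = NULL) {
  if (is.null(groups)) normfinder_ungrouped(m) else normfinder_grouped(m, groups)
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("Model-based stability (",
      if (x$grouped) "grouped" else "ungrouped", ")\n", sep = "")
  if (x$grouped) cat(sprintf("  gamma2 (between-group variance): %.5g\n", x$gamma2))
  print(x$ranking[order(x$ranking$rank), ], row.names = FALSE)
  invisible(x)
}

# accept factor/vector in sample order, named vector, or annotation df
resolve_groups <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample", "group") %in% names(groups)))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  if (!is.null(names(groups))) {
    miss <- setdiff(sample_ids, names(groups))
    if (length(miss)) stop("no group label for sample(s): ",
                           paste(miss, collapse = ", "))
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    stop("group labels must cover every sample")
  }
  as.character(groups)
}
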