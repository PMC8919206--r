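#' BestKeeper descriptive stability
#'
#' The descriptive approach: per gene, the spread of raw Cq across samples
#' (SD, coefficient of variation, range, arithmetic and geometric means) and
#' the Pearson correlation of the gene's Cq with the BestKeeper index, the
#' per-sample geometric mean of Cq over all candidates. Genes are ranked by
#' the spread statistic (lower = more stable); SD above 1 cycle is flagged
#' `inconsistent` following the classical heuristic, advisory only. Unlike
#' the ratio-based methods this statistic is sensitive to sample loading
#' differences, which is part of its descriptive character.
#'
#' @param m complete Cq matrix.
#' @param sd_estimator `"sample_sd"` (n-1 SD about the arithmetic mean,
#'   default) or `"mad_geo"` (mean absolute deviation about the geometric
#'   mean, the original tool's descriptive variant).
#' @return object of class `bestkeeper_result`: data.frame `ranking` with
#'   columns `gene`, `n`, `geo_mean`, `arith_mean`, `min`, `max`, `sd`,
#'   `cv_percent`, `r_index`, `p_value`, `inconsistent`, `rank`; vector
#'   `index` (per-sample geometric mean Cq); `sd_estimator`.
#' @export
bestkeeper <- function(m, sd_estimator = c("sample_sd", "mad_geo")) {
  m <- as_cq_matrix(m)
  sd_estimator <- match.arg(sd_estimator)
  if (anyNA(m)) stop("BestKeeper requires a complete Cq matrix")
  index <- exp(colMeans(log(m)))
  geo <- exp(rowMeans(log(m)))
  spread <- switch(sd_estimator,
    sample_sd = apply(m, 1L, stats::sd),
    mad_geo   = rowMeans(abs(m - geo))
  )
  cors <- lapply(seq_len(nrow(m)), function(j) {
    if (stats::sd(m[j, ]) == 0) {
      warning("gene '", rownames(m)[j],
              "' has zero variance; correlation with index undefined")
      list(estimate = NA_real_, p.value = NA_real_)
    } else {
      ct <- stats::cor.test(m[j, ], index)
      list(estimate = unname(ct$estimate), p.value = ct$p.value)
    }
  })
  ranking <- data.frame(
    gene = rownames(m),
    n = ncol(m),
    geo_mean = geo,
    arith_mean = rowMeans(m),
    min = apply(m, 1L, min),
    max = apply(m, 1L, max),
    sd = spread,
    cv_percent = spread / rowMeans(m) * 100,
    r_index = vapply(cors, `[[`, numeric(1), "estimate"),
    p_value = vapply(cors, `[[`, numeric(1), "p.value"),
    inconsistent = spread > 1,
    rank = rank_from_stability(spread),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(ranking = ranking, index = index,
                 sd_estimator = sd_estimator),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper descriptives (spread estimator:", x$sd_estimator, ")\n")
  print(x$ranking[order(x$ranking$rank),
                  c("gene", "arith_mean", "sd", "cv_percent", "r_index", "rank")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Comparative delta-Ct stability
#'
#' For every gene pair (j, k) the SD (n-1) across samples of the per-sample
#' Cq difference Cq_j - Cq_k; a gene's stability is the mean of its pair SDs
#' over the other G-1 genes. Two ideal references keep a constant Cq
#' difference in every sample (pair SD 0). The statistic is invariant to
#' per-sample loading shifts, and with perfect doubling it coincides with
#' the geNorm pairwise variation.
#'
#' @param m complete Cq matrix (>= 2 genes, >= 3 samples).
#' @return object of class `delta_ct_result`: data.frame `ranking` with
#'   columns `gene`, `stability`, `rank`; symmetric matrix `pair_sd`.
#' @export
delta_ct <- function(m) {
  m <- as_cq_matrix(m)
  if (anyNA(m)) stop("delta-Ct stability requires a complete Cq matrix")
  g <- nrow(m)
  if (g < 2L) stop("need >= 2 genes")
  if (ncol(m) < 3L) stop("need >= 3 samples")
  pair_sd <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(g - 1L)) {
    for (k in (j + 1L):g) {
      pair_sd[j, k] <- pair_sd[k, j] <- stats::sd(m[j, ] - m[k, ])
    }
  }
  stability <- rowSums(pair_sd) / (g - 1L)
  ranking <- data.frame(gene = rownames(m), stability = stability,
                        rank = rank_from_stability(stability),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ranking = ranking, pair_sd = pair_sd),
            class = "delta_ct_result")
}

#' @export
print.delta_ct_result <- function(x, ...) {
  cat("Comparative delta-Ct stability\n")
  print(x$ranking[order(x$ranking$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}
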