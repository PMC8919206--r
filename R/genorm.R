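#' Convert Cq values to relative quantities
#'
#' geNorm operates on relative quantities rather than raw cycles. For gene j
#' with amplification factor A_j (fold per cycle), each sample's quantity is
#' expressed relative to the sample with the lowest Cq of that gene:
#' `Q_ij = A_j ^ (min_i Cq_ij - Cq_ij)`, so Q lies in (0, 1] with Q = 1 at
#' the gene's minimum. With A = 2 (100% efficiency) one extra cycle halves Q.
#'
#' @param m Cq matrix (genes x samples, complete).
#' @param factors amplification factor per gene (fold per cycle); a scalar
#'   is recycled. Default 2 assumes perfect doubling; measured factors from
#'   [fit_standard_curve()] can be supplied per gene (named or positional).
#' @return matrix of relative quantities, same dimnames as `m`.
#' @export
relative_quantities <- function(m, factors = 2) {
  m <- as_cq_matrix(m)
  if (anyNA(m)) stop("relative quantities require a complete Cq matrix")
  if (length(factors) == 1L) factors <- rep(factors, nrow(m))
  if (!is.null(names(factors))) {
    miss <- setdiff(rownames(m), names(factors))
    if (length(miss)) stop("no amplification factor for: ",
                           paste(miss, collapse = ", "))
    factors <- factors[rownames(m)]
  }
  if (length(factors) != nrow(m)) stop("one amplification factor per gene required")
  if (any(factors <= 1)) stop("amplification factors must exceed 1")
  q <- factors ^ (apply(m, 1L, min) - m)
  dimnames(q) <- dimnames(m)
  q
}

#' geNorm pairwise variation between two genes
#'
#' The standard deviation (n-1 denominator) across samples of the log2
#' ratio of two genes' relative quantities. Two ideal reference genes have a
#' constant expression ratio, hence V = 0. With all amplification factors
#' equal to 2 this is exactly the SD of the per-sample Cq difference, the
#' comparative delta-Ct pair statistic.
#'
#' @param q relative-quantity matrix from [relative_quantities()].
#' @param gene_j,gene_k gene ids (or row indices), distinct.
#' @return nonnegative scalar.
#' @export
genorm_pair_variation <- function(q, gene_j, gene_k) {
  lj <- log2(q[gene_j, ])
  lk <- log2(q[gene_k, ])
  if (identical(gene_j, gene_k)) stop("gene_j and gene_k must differ")
  stats::sd(lj - lk)
}

# all pairwise SDs of log2 ratios; symmetric matrix with zero diagonal
pair_variation_matrix <- function(q) {
  l <- log2(q)
  g <- nrow(l)
  v <- matrix(0, g, g, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(g - 1L)) {
    for (k in (j + 1L):g) {
      v[j, k] <- v[k, j] <- stats::sd(l[j, ] - l[k, ])
    }
  }
  v
}

#' geNorm stability ranking by iterative exclusion
#'
#' A gene's expression-stability measure M is the arithmetic mean of its
#' pairwise variations with all other candidate genes. The least stable gene
#' (highest M) is removed and M is recomputed among the survivors, repeating
#' until two genes remain; those two cannot be separated (each one's M is
#' the variation of the final pair) and share rank 1. The reported M for
#' each gene is its value at the step it was excluded, which is what yields
#' the tied top pair seen in published geNorm tables.
#'
#' @param q relative-quantity matrix (>= 3 genes).
#' @return object of class `genorm_result`: data.frame `ranking` with
#'   columns `gene`, `m_value`, `rank` (competition ranks, most stable = 1),
#'   plus `stability_order` (gene ids, most stable first; the final pair in
#'   input order) and `exclusion_step` (1 = removed first).
#' @export
genorm_rank <- function(q) {
  g <- nrow(q)
  if (g < 3L) stop("geNorm ranking requires >= 3 genes")
  v <- pair_variation_matrix(q)
  genes <- rownames(q)
  alive <- rep(TRUE, g)
  m_value <- numeric(g)
  exclusion_step <- integer(g)
  removed <- character(0)
  step <- 0L
  while (sum(alive) > 2L) {
    step <- step + 1L
    idx <- which(alive)
    m <- vapply(idx, function(j) mean(v[j, setdiff(idx, j)]), numeric(1))
    # tie on max M: remove the later gene in input order (deterministic)
    worst <- idx[max(which(m == max(m)))]
    m_value[worst] <- max(m)
    exclusion_step[worst] <- step
    removed <- c(removed, genes[worst])
    alive[worst] <- FALSE
  }
  pair <- which(alive)
  final_m <- v[pair[1L], pair[2L]]
  m_value[pair] <- final_m
  exclusion_step[pair] <- step + 1L
  ranking <- data.frame(gene = genes, m_value = m_value,
                        rank = rank_from_stability(m_value),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ranking = ranking,
                 stability_order = c(genes[pair], rev(removed)),
                 exclusion_step = stats::setNames(exclusion_step, genes)),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability ranking (", nrow(x$ranking), " genes)\n", sep = "")
  ord <- order(x$ranking$rank, match(x$ranking$gene, x$stability_order))
  print(x$ranking[ord, ], row.names = FALSE)
  invisible(x)
}

#' Normalization factor over a set of reference genes
#'
#' The per-sample geometric mean of the relative quantities of the chosen
#' reference genes -- the quantity target genes are divided by when
#' normalizing.
#'
#' @param q relative-quantity matrix.
#' @param genes nonempty subset of gene ids (or indices).
#' @return named numeric vector, one NF per sample.
#' @export
normalization_factor <- function(q, genes) {
  if (length(genes) == 0L) stop("need at least one gene for a normalization factor")
  sub <- q[genes, , drop = FALSE]
  exp(colMeans(log(sub)))
}

#' Pairwise variation profile and optimal reference-gene number
#'
#' For n = 2 .. G-1, V(n, n+1) is the standard deviation across samples of
#' log2(NF_n / NF_{n+1}), where NF_n is the normalization factor over the n
#' most stable genes of the geNorm ranking. A small V means adding the
#' (n+1)-th gene hardly changes the normalization factor, so n genes
#' suffice; the conventional threshold is 0.15. The recommended number is
#' the smallest n with V below the threshold (`NA` if none); when every V is
#' already below it, the full profile still allows a judgement from the
#' trend, which is left to the analyst.
#'
#' @param q relative-quantity matrix (>= 3 genes).
#' @param ranking a `genorm_result` for `q`; computed if omitted.
#' @param threshold cutoff on V (default 0.15).
#' @return object of class `pairwise_variation_profile`: data.frame
#'   `profile` with columns `n`, `v`, `below_threshold`; `recommended_n`;
#'   `threshold`; `gene_order` used for the NF sets.
#' @export
pairwise_variation_profile <- function(q, ranking = NULL, threshold = 0.15) {
  if (nrow(q) < 3L) stop("pairwise variation requires >= 3 genes")
  if (is.null(ranking)) ranking <- genorm_rank(q)
  ord <- ranking$stability_order
  nmax <- nrow(q) - 1L
  v <- numeric(nmax - 1L)
  lq <- log2(q)
  for (n in 2:nmax) {
    nf_n <- colMeans(lq[ord[seq_len(n)], , drop = FALSE])
    nf_n1 <- colMeans(lq[ord[seq_len(n + 1L)], , drop = FALSE])
    v[n - 1L] <- stats::sd(nf_n - nf_n1)
  }
  profile <- data.frame(n = 2:nmax, v = v, below_threshold = v < threshold)
  rec <- if (any(profile$below_threshold)) {
    profile$n[which(profile$below_threshold)[1L]]
  } else NA_integer_
  structure(list(profile = profile, recommended_n = rec,
                 threshold = threshold, gene_order = ord),
            class = "pairwise_variation_profile")
}

#' @export
print.pairwise_variation_profile <- function(x, ...) {
  cat("Pairwise variation V(n, n+1), threshold", x$threshold, "\n")
  print(x$profile, row.names = FALSE)
  cat("recommended number of reference genes:",
      if (is.na(x$recommended_n)) "none below threshold" else x$recommended_n,
      "\n")
  invisible(x)
}
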