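# Shared fixtures and independent brute-force oracles. The oracles are
# written as plain loops from the definitions and never call the package
# functions they are used to check.

toy_cq <- function() {
  m <- rbind(A = c(20, 21, 22, 23),
             B = c(25, 26.1, 26.9, 28),
             C = c(18, 20, 19.5, 21.5))
  colnames(m) <- paste0("S", 1:4)
  m
}

random_cq <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes * n_samples, 15, 35), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

# SD of log2 ratio of two relative-quantity rows, from the definition
bf_pair_sd <- function(l_j, l_k) {
  d <- l_j - l_k
  mu <- sum(d) / length(d)
  sqrt(sum((d - mu)^2) / (length(d) - 1))
}

# naive geNorm: recompute every pairwise SD with loops, exclude worst
bf_genorm <- function(cq, factor = 2) {
  l <- log2(factor) * (-cq)  # log2 quantities up to per-gene constants
  genes <- rownames(cq)
  alive <- genes
  m_rec <- stats::setNames(numeric(length(genes)), genes)
  removed <- character(0)
  while (length(alive) > 2L) {
    m <- sapply(alive, function(j) {
      mean(sapply(setdiff(alive, j), function(k) bf_pair_sd(l[j, ], l[k, ])))
    })
    worst <- alive[max(which(m == max(m)))]
    m_rec[worst] <- max(m)
    removed <- c(removed, worst)
    alive <- setdiff(alive, worst)
  }
  m_rec[alive] <- bf_pair_sd(l[alive[1L], ], l[alive[2L], ])
  list(m = m_rec, order = c(alive, rev(removed)))
}

bf_deltact <- function(cq) {
  genes <- rownames(cq)
  sapply(genes, function(j) {
    mean(sapply(setdiff(genes, j), function(k) bf_pair_sd(cq[j, ], cq[k, ])))
  })
}

bf_bestkeeper <- function(cq) {
  idx <- apply(cq, 2L, function(col) prod(col)^(1 / length(col)))
  list(index = idx,
       sd = apply(cq, 1L, stats::sd),
       arith = rowMeans(cq),
       geo = apply(cq, 1L, function(x) prod(x)^(1 / length(x))),
       r = apply(cq, 1L, function(x) stats::cor(x, idx)))
}

bf_normfinder_ungrouped <- function(cq) {
  k <- nrow(cq)
  z <- cq
  for (i in seq_len(ncol(cq))) z[, i] <- cq[, i] - mean(cq[, i])
  s2 <- apply(z, 1L, function(x) sum((x - mean(x))^2) / (length(x) - 1))
  sigma2 <- pmax(0, (s2 - mean(s2) / (k - 1)) * k / (k - 2))
  sqrt(sigma2)
}

# V profile from the definition, given the gene stability order
bf_v_profile <- function(q, ord) {
  lq <- log2(q)
  vapply(2:(nrow(q) - 1L), function(n) {
    nf_n <- apply(lq[ord[1:n], , drop = FALSE], 2L, mean)
    nf_n1 <- apply(lq[ord[1:(n + 1L)], , drop = FALSE], 2L, mean)
    bf_pair_sd(nf_n, nf_n1)
  }, numeric(1))
}

# Cq matrix constructed (orthogonal Walsh patterns over 8 samples) so the
# pairwise-variation profile first drops below 0.15 at n = 4
constructed_v4_matrix <- function() {
  p1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  p2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  p3 <- c(1, -1, -1, 1, 1, -1, -1, 1)
  p4 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  s <- stats::sd(p1)
  l3 <- 0.6 / s * p1
  l4 <- 0.7 / s * p2
  l5 <- (l3 + l4) / 4 + 0.65 / s * p3
  l6 <- 3 / s * p4
  cq <- 25 - rbind(g1 = rep(0, 8), g2 = rep(0, 8), g3 = l3, g4 = l4,
                   g5 = l5, g6 = l6)
  colnames(cq) <- paste0("S", 1:8)
  cq
}

# per-condition rank matrix from the published fixture
published_rank_matrix <- function(pr, cond) {
  sub <- pr[pr$condition == cond, ]
  data.frame(gene = sub$gene, genorm = sub$genorm_rank,
             normfinder = sub$normfinder_rank,
             bestkeeper = sub$bestkeeper_rank,
             deltact = sub$deltact_rank, stringsAsFactors = FALSE)
}

published_order_vector <- function(po, cond) {
  sub <- po[po$condition == cond, ]
  sub$gene[order(sub$position)]
}
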