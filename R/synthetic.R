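#' Simulate a replicate-level Cq experiment with known ground truth
#'
#' Generates quantification-cycle data under the additive log-scale model
#' `Cq_ijr = B_j + L_i + Delta_{g(i),j} + eps_ij + tau_ijr`, with gene
#' baseline B_j (cycles), per-sample loading offset L_i ~ N(0, loading_sd^2)
#' (RNA input / pipetting differences shared by all genes of a sample),
#' optional condition effect Delta for gene j in sample i's group, biological
#' noise eps_ij ~ N(0, sigma_j^2) drawn once per (gene, sample), and
#' technical noise tau ~ N(0, tech_sd^2) per replicate. Cq is a log-scale
#' measure of expression, so multiplicative expression noise is additive
#' here. Defaults mirror a 12-gene x 36-sample x 3-replicate validation
#' design, with baselines spread over the Cq range typical of abundant to
#' scarce transcripts and per-gene noise SDs spanning clearly stable to
#' clearly unstable candidates.
#'
#' @param n_genes,n_samples,n_reps design dimensions (defaults 12, 36, 3).
#' @param baselines gene baseline Cq values B_j (default: evenly spread over
#'   12..32 cycles).
#' @param loading_sd SD of the per-sample loading offset, cycles (default 1).
#' @param gene_noise_sd per-gene biological noise SD sigma_j, cycles
#'   (default: evenly spread over 0.05..1.2; scalar recycled).
#' @param tech_sd technical replicate SD, cycles (default 0.1).
#' @param groups optional group label per sample (length `n_samples`);
#'   default one group `"all"`.
#' @param group_effects optional genes x groups matrix of condition effects
#'   Delta in cycles (default all zero). Column order follows
#'   `unique(groups)`.
#' @param seed RNG seed for reproducibility (fixed seed gives identical
#'   output).
#' @return object of class `synthetic_cq_experiment`: `replicates`
#'   (long-layout data.frame `sample`, `gene`, `replicate`, `cq`, `group`),
#'   `annotation` (`sample`, `group`, `replicate_id`), and `truth` (list
#'   with `baselines`, `loading`, `gene_noise_sd`, `tech_sd`,
#'   `group_effects`, and `stable_order`, the gene ids in ascending true
#'   noise among genes without condition effects).
#' @export
simulate_cq_experiment <- function(n_genes = 12, n_samples = 36, n_reps = 3,
                                   baselines = NULL, loading_sd = 1,
                                   gene_noise_sd = NULL, tech_sd = 0.1,
                                   groups = NULL, group_effects = NULL,
                                   seed = NULL) {
  if (n_genes < 2 || n_samples < 3 || n_reps < 1) {
    stop("invalid design: need >= 2 genes, >= 3 samples, >= 1 replicate")
  }
  if (loading_sd < 0 || tech_sd < 0) stop("SDs must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%02d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples))
  if (is.null(baselines)) baselines <- seq(12, 32, length.out = n_genes)
  if (is.null(gene_noise_sd)) {
    gene_noise_sd <- seq(0.05, 1.2, length.out = n_genes)
  }
  if (length(gene_noise_sd) == 1L) gene_noise_sd <- rep(gene_noise_sd, n_genes)
  stopifnot(length(baselines) == n_genes, length(gene_noise_sd) == n_genes,
            all(gene_noise_sd >= 0))
  if (is.null(groups)) groups <- rep("all", n_samples)
  stopifnot(length(groups) == n_samples)
  glev <- unique(groups)
  if (is.null(group_effects)) {
    group_effects <- matrix(0, n_genes, length(glev))
  }
  stopifnot(nrow(group_effects) == n_genes, ncol(group_effects) == length(glev))
  dimnames(group_effects) <- list(genes, glev)
  names(baselines) <- names(gene_noise_sd) <- genes

  loading <- stats::rnorm(n_samples, 0, loading_sd)
  names(loading) <- samples
  eps <- matrix(stats::rnorm(n_genes * n_samples), n_genes) * gene_noise_sd
  gidx <- match(groups, glev)
  mean_cq <- baselines + outer(rep(1, n_genes), loading) +
    group_effects[, gidx, drop = FALSE] + eps

  reps <- expand.grid(replicate = seq_len(n_reps), gene = genes,
                      sample = samples, stringsAsFactors = FALSE)
  reps <- reps[, c("sample", "gene", "replicate")]
  reps$cq <- mean_cq[cbind(match(reps$gene, genes), match(reps$sample, samples))] +
    stats::rnorm(nrow(reps), 0, tech_sd)
  reps$group <- groups[match(reps$sample, samples)]
  rownames(reps) <- NULL

  no_effect <- genes[rowSums(group_effects != 0) == 0L]
  structure(list(
    replicates = reps,
    annotation = data.frame(sample = samples, group = groups,
                            replicate_id = samples, stringsAsFactors = FALSE),
    truth = list(baselines = baselines, loading = loading,
                 gene_noise_sd = gene_noise_sd, tech_sd = tech_sd,
                 group_effects = group_effects,
                 stable_order = no_effect[order(gene_noise_sd[no_effect])])
  ), class = "synthetic_cq_experiment")
}

#' Simulate a dilution-series standard curve
#'
#' Six 10-fold serial dilutions spanning 1e4..1e9 copies/uL by default,
#' with `Cq = intercept - log10(amount) / log10(true_factor) + noise`, so a
#' noiseless series fitted with [fit_standard_curve()] returns the true
#' amplification factor exactly.
#'
#' @param true_factor true fold amplification per cycle (> 1).
#' @param intercept Cq at log10(amount) = 0 (default 40 cycles).
#' @param noise_sd Gaussian Cq noise SD (default 0).
#' @param n_points number of 10-fold dilutions starting at 1e4 (default 6).
#' @param gene gene id carried into the output (default `"assay"`).
#' @param seed RNG seed.
#' @return data.frame with columns `gene`, `log10_amount`, `cq`.
#' @export
simulate_standard_curve <- function(true_factor = 2, intercept = 40,
                                    noise_sd = 0, n_points = 6,
                                    gene = "assay", seed = NULL) {
  if (true_factor <= 1) stop("true_factor must exceed 1")
  if (!is.null(seed)) set.seed(seed)
  x <- seq(4, length.out = n_points)
  cq <- intercept - x / log10(true_factor) +
    stats::rnorm(n_points, 0, noise_sd)
  data.frame(gene = gene, log10_amount = x, cq = cq,
             stringsAsFactors = FALSE)
}

#' Simulate a TPM matrix with families and planted filter violations
#'
#' Log-normal TPM values (genes x stages) organized into gene families,
#' with designated genes constructed to violate the low-expression filter
#' (TPM below 5 in two stages), to fail the abundance criterion (never
#' above 1000), or to be each family's intended winner (abundant and with
#' the smallest expression dispersion). The returned truth table makes the
#' candidate-selection pipeline verifiable end to end.
#'
#' @param n_stages number of stages/columns (default 16, an embryonic
#'   time-course scale).
#' @param family_sizes named integer vector: genes per family (default 8
#'   families of 2-4 homologs).
#' @param seed RNG seed.
#' @return list with `tpm` (matrix), `families` (named vector), `truth`
#'   (data.frame `gene`, `family`, `role` in
#'   `c("winner", "low_expression", "not_abundant", "noisy")`).
#' @export
simulate_tpm_matrix <- function(n_stages = 16, family_sizes = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(family_sizes)) {
    family_sizes <- stats::setNames(rep(c(3L, 2L, 4L, 3L), 2L),
                                    c("Actin", "RPL", "Tubulin", "GAPDH",
                                      "RPS", "EF1A", "TATA", "HSP"))
  }
  rows <- list(); fams <- character(0); roles <- list()
  for (f in names(family_sizes)) {
    sz <- family_sizes[[f]]
    # roles within a family: one intended winner, the rest drawn from the
    # violation types, cycling
    role <- c("winner", rep(c("noisy", "not_abundant", "low_expression"),
                            length.out = sz - 1L))
    for (i in seq_len(sz)) {
      g <- sprintf("%s_h%d", f, i)
      base <- switch(role[i],
        winner = stats::runif(1, 2000, 6000),
        noisy = stats::runif(1, 2000, 6000),
        not_abundant = stats::runif(1, 50, 500),
        low_expression = stats::runif(1, 1000, 3000))
      cv <- switch(role[i], winner = 0.05, noisy = 0.6,
                   not_abundant = 0.2, low_expression = 0.2)
      x <- base * exp(stats::rnorm(n_stages, 0, cv) - cv^2 / 2)
      if (role[i] == "low_expression") x[1:2] <- stats::runif(2, 0.1, 4.9)
      if (role[i] == "not_abundant") x <- pmin(x, 900)
      rows[[g]] <- x
      fams[g] <- f
      roles[[g]] <- role[i]
    }
  }
  tpm <- do.call(rbind, rows)
  colnames(tpm) <- sprintf("stage%02d", seq_len(n_stages))
  list(tpm = tpm, families = fams,
       truth = data.frame(gene = names(roles), family = unname(fams),
                          role = unlist(roles), stringsAsFactors = FALSE,
                          row.names = NULL))
}
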