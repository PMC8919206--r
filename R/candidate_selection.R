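#' Filter lowly expressed genes from a TPM matrix
#'
#' Pre-selection step on RNA-seq quantification: a gene with TPM below the
#' floor in at least `max_low_stages` stages is removed from the candidate
#' pool (defaults: TPM < 5 in >= 2 stages).
#'
#' @param tpm numeric matrix, genes x stages, TPM values (>= 0).
#' @param tpm_floor expression floor (default 5).
#' @param max_low_stages number of below-floor stages that triggers removal
#'   (default 2).
#' @return the filtered matrix (surviving genes, original order).
#' @export
filter_low_expression <- function(tpm, tpm_floor = 5, max_low_stages = 2) {
  tpm <- as_expression_matrix(tpm)
  low <- rowSums(tpm < tpm_floor)
  tpm[low < max_low_stages, , drop = FALSE]
}

#' Variance-stabilizing transform for TPM values
#'
#' A monotone per-value transform flattening the mean-variance relationship
#' of expression data so that SDs of high and low expressors are comparable.
#' Default `log2p1` is log2(tpm + 1); `anscombe` is the square-root-family
#' alternative 2*sqrt(tpm + 3/8) suited to count-like data.
#'
#' @param tpm nonnegative matrix (genes x stages).
#' @param method `"log2p1"` or `"anscombe"`.
#' @return transformed matrix, same dimnames.
#' @export
variance_stabilize <- function(tpm, method = c("log2p1", "anscombe")) {
  method <- match.arg(method)
  tpm <- as_expression_matrix(tpm)
  switch(method,
         log2p1 = log2(tpm + 1),
         anscombe = 2 * sqrt(tpm + 3 / 8))
}

#' Rank genes by expression SD within families
#'
#' The SD (n-1) of each gene's transformed expression across stages, with
#' ascending competition ranks within each gene family (homolog group);
#' the lowest-SD homolog is the preferred candidate of its family.
#'
#' @param vst transformed expression matrix (e.g. from
#'   [variance_stabilize()]).
#' @param families named character vector or data.frame (`gene`, `family`)
#'   mapping each gene to exactly one family.
#' @return data.frame with columns `family`, `gene`, `sd_vst`,
#'   `rank_in_family`.
#' @export
rank_by_sd <- function(vst, families) {
  vst <- as_expression_matrix(vst)
  fam <- resolve_families(families, rownames(vst))
  sds <- apply(vst, 1L, stats::sd)
  out <- data.frame(family = fam, gene = rownames(vst), sd_vst = sds,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank_in_family <- stats::ave(out$sd_vst, out$family,
                                   FUN = function(x) rank(x, ties.method = "min"))
  out[order(match(out$family, unique(out$family)), out$rank_in_family), ,
      drop = FALSE]
}

#' Select one candidate reference gene per family
#'
#' Applies the two published selection criteria to an already
#' low-expression-filtered TPM matrix: within each family the chosen
#' candidate is the gene with the lowest SD of variance-stabilized
#' expression among those abundantly expressed (raw TPM above `tpm_high` in
#' at least `min_high_stages` stages). A family with no qualifying gene is
#' reported empty with the reason. SD ties resolve to the first gene in
#' input order (recorded in `reason`).
#'
#' @param tpm raw TPM matrix, already passed through
#'   [filter_low_expression()].
#' @param families gene-to-family map (see [rank_by_sd()]).
#' @param tpm_high abundance threshold (default 1000).
#' @param min_high_stages stages required above the threshold (default 8).
#' @param vst_method transform passed to [variance_stabilize()].
#' @return data.frame with one row per (family, gene): `family`, `gene`,
#'   `sd_vst`, `n_high_stages`, `selected`, `reason`.
#' @export
select_candidates <- function(tpm, families, tpm_high = 1000,
                              min_high_stages = 8, vst_method = "log2p1") {
  tpm <- as_expression_matrix(tpm)
  fam <- resolve_families(families, rownames(tpm))
  vst <- variance_stabilize(tpm, vst_method)
  sds <- apply(vst, 1L, stats::sd)
  n_high <- rowSums(tpm > tpm_high)
  rows <- list()
  for (f in unique(fam)) {
    idx <- which(fam == f)
    qual <- idx[n_high[idx] >= min_high_stages]
    chosen <- if (length(qual)) qual[which.min(sds[qual])] else NA_integer_
    for (i in idx) {
      reason <- if (is.na(chosen)) {
        "family empty: no gene abundant in enough stages"
      } else if (i == chosen) {
        if (sum(sds[qual] == sds[chosen]) > 1L) {
          "selected: lowest SD among qualifying homologs (tie, first in input order)"
        } else "selected: lowest SD among qualifying homologs"
      } else if (n_high[i] < min_high_stages) {
        sprintf("abundance criterion failed (TPM > %g in %d < %d stages)",
                tpm_high, n_high[i], min_high_stages)
      } else "higher SD than selected homolog"
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, gene = rownames(tpm)[i], sd_vst = sds[i],
        n_high_stages = n_high[i],
        selected = !is.na(chosen) && i == chosen, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (identical(names(x)[1L], "gene")) {
      rn <- as.character(x[[1L]])
      x <- as.matrix(x[, -1L, drop = FALSE])
      rownames(x) <- rn
    } else x <- as.matrix(x)
  }
  if (!is.numeric(x) || is.null(rownames(x))) {
    stop("expression data must be a numeric matrix with gene rownames")
  }
  if (any(x < 0, na.rm = TRUE)) stop("negative expression values")
  x
}

resolve_families <- function(families, gene_ids) {
  if (is.data.frame(families)) {
    stopifnot(all(c("gene", "family") %in% names(families)))
    families <- stats::setNames(as.character(families$family),
                                as.character(families$gene))
  }
  miss <- setdiff(gene_ids, names(families))
  if (length(miss)) stop("no family for gene(s): ", paste(miss, collapse = ", "))
  unname(families[gene_ids])
}
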