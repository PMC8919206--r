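#' Competition ranks from stability values
#'
#' Lower stability = more stable = rank 1. Ties share the minimum rank and
#' the following rank skips by the tie size (1, 1, 3, ...), the convention
#' of published stability tables.
#'
#' @param values per-gene stability values (finite).
#' @param ascending if `FALSE`, higher values get rank 1.
#' @return integer ranks, names preserved.
#' @export
rank_from_stability <- function(values, ascending = TRUE) {
  if (any(!is.finite(values))) stop("stability values must be finite")
  v <- if (ascending) values else -values
  r <- rank(v, ties.method = "min")
  storage.mode(r) <- "integer"
  r
}

#' Aggregate method rankings by geometric mean (comprehensive ranking)
#'
#' The RefFinder-style comprehensive evaluation: given each method's
#' competition ranks over the same gene set, a gene's aggregate score is the
#' geometric mean of its ranks, `(r1 * ... * rM)^(1/M)`, and the final order
#' is ascending in that score. Score ties are broken deterministically by
#' (i) arithmetic mean rank, then (ii) the `normfinder` method's rank if
#' that method is present, then (iii) input gene order; each criterion is
#' applied only when the previous one ties, and every invoked tie-break is
#' recorded.
#'
#' @param rankings the per-method ranks: a named list of named rank vectors,
#'   a data.frame/matrix with genes in rows and one column per method, or a
#'   list of `MethodRanking`-like data.frames with `gene` and `rank`
#'   columns. At least two methods covering an identical gene set.
#' @return object of class `aggregate_ranking`: data.frame `ranking` with
#'   the per-method rank columns, `geo_mean` and `final_rank`, ordered most
#'   stable first; character vector `ordering`; `tie_breaks` log.
#' @export
aggregate_geometric <- function(rankings) {
  rmat <- as_rank_matrix(rankings)
  if (ncol(rmat) < 2L) stop("aggregation requires >= 2 method rankings")
  genes <- rownames(rmat)
  geo <- exp(rowMeans(log(rmat)))
  mean_rank <- rowMeans(rmat)
  nf <- if ("normfinder" %in% colnames(rmat)) rmat[, "normfinder"] else
    rep(0, length(genes))
  ord <- order(geo, mean_rank, nf, seq_along(genes))
  # log which tie-break level separated adjacent genes, if any
  tie_breaks <- character(0)
  tol <- 1e-12
  for (i in seq_len(length(ord) - 1L)) {
    a <- ord[i]; b <- ord[i + 1L]
    if (abs(geo[a] - geo[b]) < tol) {
      lvl <- if (abs(mean_rank[a] - mean_rank[b]) >= tol) "mean rank"
      else if (abs(nf[a] - nf[b]) >= tol) "normfinder rank"
      else "input order"
      tie_breaks <- c(tie_breaks,
                      sprintf("%s before %s by %s", genes[a], genes[b], lvl))
    }
  }
  out <- data.frame(gene = genes, rmat, geo_mean = geo,
                    final_rank = rank(geo, ties.method = "min"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(ranking = out, ordering = out$gene, tie_breaks = tie_breaks),
            class = "aggregate_ranking")
}

#' @export
print.aggregate_ranking <- function(x, ...) {
  cat("Comprehensive (geometric-mean) ranking\n")
  print(x$ranking, row.names = FALSE, digits = 4)
  if (length(x$tie_breaks)) {
    cat("tie-breaks:", paste(x$tie_breaks, collapse = "; "), "\n")
  }
  invisible(x)
}

# normalize the accepted ranking inputs to a genes x methods matrix
as_rank_matrix <- function(rankings) {
  if (is.matrix(rankings) || is.data.frame(rankings)) {
    if (is.data.frame(rankings) && "gene" %in% names(rankings)) {
      rn <- rankings$gene
      rankings <- rankings[setdiff(names(rankings), "gene")]
      rownames(rankings) <- rn
    }
    rmat <- as.matrix(rankings)
  } else if (is.list(rankings)) {
    vecs <- lapply(rankings, function(r) {
      if (is.data.frame(r)) stats::setNames(r$rank, r$gene)
      else if (inherits(r, c("genorm_result", "normfinder_result",
                             "bestkeeper_result", "delta_ct_result"))) {
        stats::setNames(r$ranking$rank, r$ranking$gene)
      } else r
    })
    genes <- names(vecs[[1L]])
    if (is.null(genes)) stop("rank vectors must be named by gene")
    for (i in seq_along(vecs)) {
      diff <- c(setdiff(genes, names(vecs[[i]])), setdiff(names(vecs[[i]]), genes))
      if (length(diff)) {
        stop("method rankings cover different gene sets; differing: ",
             paste(unique(diff), collapse = ", "))
      }
      vecs[[i]] <- vecs[[i]][genes]
    }
    rmat <- do.call(cbind, vecs)
    rownames(rmat) <- genes
  } else stop("unsupported rankings input")
  if (is.null(rownames(rmat))) stop("rank matrix must carry gene rownames")
  if (any(!is.finite(rmat)) || any(rmat < 1)) stop("ranks must be finite and >= 1")
  rmat
}

#' Compare an aggregated ordering with a published one
#'
#' Aggregates per-method ranks via [aggregate_geometric()] and reports
#' whether the resulting order equals a stated overall ordering, with the
#' first divergence when it does not.
#'
#' @param rankings as in [aggregate_geometric()].
#' @param printed_order character vector, most stable gene first.
#' @return list with `match` (logical), `ordering` (computed),
#'   `first_divergence` (NULL, or list with `position`, `computed`,
#'   `expected`).
#' @export
reproduce_condition_ordering <- function(rankings, printed_order) {
  agg <- aggregate_geometric(rankings)
  computed <- agg$ordering
  if (length(computed) != length(printed_order)) {
    stop("gene count mismatch between rankings and printed order")
  }
  div <- which(computed != printed_order)
  list(match = length(div) == 0L,
       ordering = computed,
       first_divergence = if (length(div)) {
         list(position = div[1L], computed = computed[div[1L]],
              expected = printed_order[div[1L]])
       } else NULL)
}

#' Published per-method stability ranks (pharaoh-ant validation study)
#'
#' The per-method stability values and competition ranks for the 12
#' candidate reference genes of *Monomorium pharaonis* across seven
#' experimental conditions (embryonic, sexual and worker development, adult
#' phenotypes, gyne/queen tissues, dsRNA injection, starvation), as printed
#' in a published RT-qPCR reference-gene validation study in that species.
#' These are the inputs of the comprehensive-ranking layer and the fixture
#' for its verification.
#'
#' @return data.frame with columns `condition`, `gene`, and per method
#'   (`genorm`, `normfinder`, `bestkeeper`, `deltact`) a `<method>_stability`
#'   and `<method>_rank` column.
#' @export
published_method_ranks <- function() {
  path <- system.file("extdata", "published_method_ranks.tsv",
                      package = "refstab", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published overall stability orderings
#'
#' The overall (comprehensively aggregated) stability orderings printed for
#' the seven conditions accompanying [published_method_ranks()].
#'
#' @return data.frame with columns `condition`, `position`, `gene`.
#' @export
published_orderings <- function() {
  path <- system.file("extdata", "published_orderings.tsv",
                      package = "refstab", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
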