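#' Coerce to a Cq matrix
#'
#' A Cq matrix is a plain numeric matrix of quantification-cycle (Cq, also
#' written Ct) values with genes in rows and samples in columns; row and
#' column names are mandatory and unique. Every stability method in this
#' package consumes this representation.
#'
#' @param x numeric matrix or data.frame (genes x samples) with rownames =
#'   gene ids and colnames = sample ids. A data.frame whose first column is
#'   named `gene` is converted with that column as rownames.
#' @return numeric matrix with unique dimnames.
#' @export
as_cq_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (identical(names(x)[1L], "gene")) {
      rn <- as.character(x[[1L]])
      x <- as.matrix(x[, -1L, drop = FALSE])
      rownames(x) <- rn
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("Cq data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("Cq matrix requires gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids in Cq matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in Cq matrix")
  x
}

#' Read a Cq table from TSV/CSV
#'
#' Two layouts are supported. `wide`: first column header `gene`, remaining
#' headers are sample ids, one row per gene -- returned as a Cq matrix.
#' `long`: replicate-level records with required headers `sample`, `gene`,
#' `replicate`, `cq` and optional `group` -- returned as a replicate table
#' (data.frame) to be collapsed with [average_technical_replicates()].
#' Gene and sample order is preserved as first seen in the file.
#'
#' @param path file path; field separator inferred from the extension
#'   (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param layout `"wide"` or `"long"`.
#' @param sep optional field separator override.
#' @param allow_missing if `FALSE`, any missing (NA) Cq cell is an error.
#' @return numeric matrix (wide) or data.frame with columns
#'   `sample`, `gene`, `replicate`, `cq` (long).
#' @export
read_cq_table <- function(path, layout = c("wide", "long"), sep = NULL,
                          allow_missing = TRUE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (!identical(names(raw)[1L], "gene")) {
      stop("wide layout requires first column header 'gene', got '",
           names(raw)[1L], "'")
    }
    if (anyDuplicated(raw$gene)) {
      stop("duplicate gene rows in wide table: ",
           paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", "))
    }
    genes <- raw$gene
    samples <- names(raw)[-1L]
    m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      m[, j] <- parse_cq_column(raw[[j + 1L]], genes, samples[j])
    }
    if (!allow_missing && anyNA(m)) stop("missing Cq values present")
    m
  } else {
    need <- c("sample", "gene", "replicate", "cq")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      stop("long layout requires headers ", paste(need, collapse = ", "),
           "; missing: ", paste(miss, collapse = ", "))
    }
    cq <- parse_cq_column(raw$cq, paste(raw$gene, raw$sample, sep = "/"), "cq")
    if (!allow_missing && anyNA(cq)) stop("missing Cq values present")
    out <- data.frame(sample = raw$sample, gene = raw$gene,
                      replicate = as.integer(raw$replicate), cq = cq,
                      stringsAsFactors = FALSE)
    if (!is.null(raw$group)) out$group <- raw$group
    dup <- duplicated(out[c("sample", "gene", "replicate")])
    if (any(dup)) {
      stop("duplicate (sample, gene, replicate) records, first at row ",
           which(dup)[1L])
    }
    out
  }
}

# strict numeric parse; "NA"/"" become NA, anything else non-numeric errors
# with the offending row/column named
parse_cq_column <- function(chr, row_ids, col_id) {
  chr <- trimws(chr)
  chr[chr == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(val) & !is.na(chr) & chr != "NA")
  if (length(bad)) {
    stop("malformed numeric cell '", chr[bad[1L]], "' at row '",
         row_ids[bad[1L]], "', column '", col_id, "'")
  }
  val
}

#' Write a Cq table
#'
#' Inverse of [read_cq_table()]; used for round-trip I/O.
#'
#' @param x Cq matrix (wide) or replicate data.frame (long).
#' @param path output path; separator from extension as in [read_cq_table()].
#' @param sep optional separator override.
#' @export
write_cq_table <- function(x, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.matrix(x)) {
    df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- x
  }
  # serialize doubles at full precision so read-back is bit-identical
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.17g", df[[j]]))
    }
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average technical replicates
#'
#' Collapses a replicate-level Cq table to a genes x samples matrix by
#' arithmetic mean of each (gene, sample) cell's replicate Cq values, the
#' standard treatment of technical replicates before stability analysis.
#' No outlier rejection is applied.
#'
#' @param reps data.frame with columns `sample`, `gene`, `replicate`, `cq`.
#' @return numeric matrix, genes x samples, in first-seen order.
#' @export
average_technical_replicates <- function(reps) {
  stopifnot(is.data.frame(reps),
            all(c("sample", "gene", "cq") %in% names(reps)))
  genes <- unique(reps$gene)
  samples <- unique(reps$sample)
  key <- interaction(factor(reps$gene, genes), factor(reps$sample, samples),
                     drop = FALSE)
  means <- tapply(reps$cq, key, mean)
  m <- matrix(as.numeric(means), nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (anyNA(m) && !anyNA(reps$cq)) {
    warning("some (gene, sample) cells have no replicates; left as NA")
  }
  m
}

#' Validate a Cq matrix
#'
#' Checks dimensions, missingness and the plausible Cq range and returns a
#' report of violations rather than throwing, so callers decide how strict
#' to be. An empty report means the matrix is fit for stability analysis.
#'
#' @param m Cq matrix.
#' @param min_genes,min_samples minimum dimensions required downstream
#'   (defaults: 2 genes, 3 samples).
#' @param cq_range valid half-open interval for Cq values; the default
#'   `(0, 45]` sits above a conventional 40-cycle protocol.
#' @return data.frame with columns `type`, `gene`, `sample`, `message`;
#'   zero rows when the matrix passes.
#' @export
validate_cq_matrix <- function(m, min_genes = 2, min_samples = 3,
                               cq_range = c(0, 45)) {
  m <- as_cq_matrix(m)
  v <- list()
  add <- function(type, gene, sample, msg) {
    v[[length(v) + 1L]] <<- data.frame(type = type, gene = gene,
                                       sample = sample, message = msg,
                                       stringsAsFactors = FALSE)
  }
  if (nrow(m) < min_genes) {
    add("dimension", NA, NA,
        sprintf("%d gene(s); at least %d required", nrow(m), min_genes))
  }
  if (ncol(m) < min_samples) {
    add("dimension", NA, NA,
        sprintf("%d sample(s); at least %d required", ncol(m), min_samples))
  }
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) {
    for (i in seq_len(nrow(idx))) {
      add("missing", rownames(m)[idx[i, 1L]], colnames(m)[idx[i, 2L]],
          "missing Cq value")
    }
  }
  bad <- which(!is.na(m) & (m <= cq_range[1L] | m > cq_range[2L] |
                              !is.finite(m)), arr.ind = TRUE)
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      add("range", rownames(m)[bad[i, 1L]], colnames(m)[bad[i, 2L]],
          sprintf("Cq %.4g outside (%g, %g]", m[bad[i, 1L], bad[i, 2L]],
                  cq_range[1L], cq_range[2L]))
    }
  }
  if (length(v)) do.call(rbind, v) else {
    data.frame(type = character(), gene = character(), sample = character(),
               message = character(), stringsAsFactors = FALSE)
  }
}

#' Drop samples with missing Cq values
#'
#' Stability methods require complete cases; samples carrying any missing
#' gene are removed (with a message naming them).
#'
#' @param m Cq matrix, possibly with NA cells.
#' @return complete-case Cq matrix.
#' @export
drop_incomplete_samples <- function(m) {
  m <- as_cq_matrix(m)
  bad <- colSums(is.na(m)) > 0L
  if (any(bad)) {
    message("dropping ", sum(bad), " sample(s) with missing Cq: ",
            paste(colnames(m)[bad], collapse = ", "))
    m <- m[, !bad, drop = FALSE]
  }
  m
}
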