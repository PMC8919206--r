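#' Run the full reference-gene stability workflow
#'
#' Orchestrates the analysis pipeline: technical-replicate averaging (when
#' replicate-level input is given), validation, complete-case filtering,
#' the requested stability methods, comprehensive rank aggregation, and the
#' geNorm pairwise-variation profile. Deterministic given its inputs.
#'
#' @param cq Cq matrix (genes x samples), or a replicate-level data.frame as
#'   returned by [read_cq_table()] with `layout = "long"`.
#' @param methods subset of `c("genorm", "normfinder", "bestkeeper",
#'   "deltact")`; all four by default.
#' @param factors amplification factor(s) for the geNorm transform
#'   (default 2).
#' @param groups optional sample group labels for the model-based method.
#' @param sd_estimator BestKeeper spread estimator (see [bestkeeper()]).
#' @param threshold pairwise-variation cutoff (default 0.15).
#' @return object of class `stability_report`: list with `methods` (named
#'   list of per-method result objects), `aggregate` (an
#'   `aggregate_ranking`, or NULL with a warning if fewer than two methods),
#'   `v_profile` (a `pairwise_variation_profile`, when geNorm ran),
#'   `cq` (the analyzed matrix) and `metadata` (config echo and warnings).
#' @export
run_stability_workflow <- function(cq,
                                   methods = c("genorm", "normfinder",
                                               "bestkeeper", "deltact"),
                                   factors = 2, groups = NULL,
                                   sd_estimator = "sample_sd",
                                   threshold = 0.15) {
  methods <- match.arg(methods, several.ok = TRUE)
  warnings <- character(0)
  if (is.data.frame(cq) && all(c("sample", "gene", "replicate", "cq") %in% names(cq))) {
    if (is.null(groups) && !is.null(cq$group)) {
      g <- stats::setNames(cq$group, cq$sample)[!duplicated(cq$sample)]
      if (length(unique(g)) >= 2L) groups <- g
    }
    cq <- average_technical_replicates(cq)
  }
  m <- as_cq_matrix(cq)
  report <- validate_cq_matrix(m)
  issues <- report[report$type != "missing", , drop = FALSE]
  if (nrow(issues)) {
    stop("stage validate: Cq matrix failed validation (first: ",
         issues$message[1L], ")")
  }
  m <- drop_incomplete_samples(m)
  if (ncol(m) < 3L) stop("stage validate: fewer than 3 complete samples")

  results <- list()
  if ("genorm" %in% methods) {
    q <- relative_quantities(m, factors)
    results$genorm <- genorm_rank(q)
  }
  if ("normfinder" %in% methods) results$normfinder <- normfinder(m, groups)
  if ("bestkeeper" %in% methods) results$bestkeeper <- bestkeeper(m, sd_estimator)
  if ("deltact" %in% methods) results$deltact <- delta_ct(m)

  aggregate <- NULL
  if (length(results) >= 2L) {
    aggregate <- aggregate_geometric(results)
  } else {
    warnings <- c(warnings, "aggregation skipped: fewer than 2 methods")
    warning("aggregation skipped: fewer than 2 methods requested")
  }
  v_profile <- NULL
  if ("genorm" %in% methods && nrow(m) >= 3L) {
    v_profile <- pairwise_variation_profile(q, results$genorm, threshold)
  }
  structure(list(
    methods = results, aggregate = aggregate, v_profile = v_profile, cq = m,
    metadata = list(
      package_version = as.character(utils::packageVersion("refstab")),
      methods = methods, factors = factors,
      grouped = !is.null(groups), sd_estimator = sd_estimator,
      threshold = threshold, n_genes = nrow(m), n_samples = ncol(m),
      warnings = warnings)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report:", x$metadata$n_genes, "genes x",
      x$metadata$n_samples, "samples; methods:",
      paste(names(x$methods), collapse = ", "), "\n")
  if (!is.null(x$aggregate)) {
    cat("overall order:", paste(x$aggregate$ordering, collapse = " > "), "\n")
  }
  if (!is.null(x$v_profile)) {
    cat("recommended reference-gene number:",
        if (is.na(x$v_profile$recommended_n)) "none below threshold"
        else x$v_profile$recommended_n, "\n")
  }
  invisible(x)
}

#' Write a stability report to disk
#'
#' Emits one TSV per method (`genorm.tsv`, `normfinder.tsv`,
#' `bestkeeper.tsv`, `deltact.tsv`), `aggregate.tsv`,
#' `pairwise_variation.tsv`, and a `report.json` summary carrying the run
#' metadata, so a run can be audited and re-executed.
#'
#' @param report a `stability_report`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)
  for (meth in names(report$methods)) {
    df <- report$methods[[meth]]$ranking
    if (meth == "genorm") names(df)[names(df) == "m_value"] <- "m_value"
    paths <- c(paths, tsv(df, paste0(meth, ".tsv")))
  }
  if (!is.null(report$aggregate)) {
    paths <- c(paths, tsv(report$aggregate$ranking, "aggregate.tsv"))
  }
  if (!is.null(report$v_profile)) {
    paths <- c(paths, tsv(report$v_profile$profile, "pairwise_variation.tsv"))
  }
  summary <- list(
    metadata = report$metadata,
    recommended_n = if (is.null(report$v_profile)) NULL else
      report$v_profile$recommended_n,
    ordering = if (is.null(report$aggregate)) NULL else
      report$aggregate$ordering,
    tie_breaks = if (is.null(report$aggregate)) NULL else
      report$aggregate$tie_breaks)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, jp))
}
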