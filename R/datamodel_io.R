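#' Construct a cohort object
#'
#' A cohort bundles a log2-scale expression matrix (genes x samples) with a
#' clinical table carrying overall survival and optional recurrence-free
#' survival, covariates and chemotherapy response. Expression columns and
#' clinical rows must describe the same samples in the same order; this
#' constructor enforces that and all other invariants.
#'
#' @param name Cohort name (single string).
#' @param expression Numeric matrix, genes in rows (unique rownames), samples
#'   in columns (unique colnames), all values finite, log2-scale.
#' @param clinical `data.frame` with columns `sample_id`, `os_time` (days,
#'   positive), `os_event` (0/1) and optionally `rfs_time`, `rfs_event`,
#'   `chemo_response` (CR/PR/SD/PD/NA) and free covariate columns.
#' @return An object of class `grp_cohort`.
#' @seealso [load_cohort()] to read a cohort from TSV files.
#' @export
cohort <- function(name, expression, clinical) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("`expression` must be a numeric matrix")
  if (nrow(expression) < 2L || ncol(expression) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  gid <- rownames(expression)
  sid <- colnames(expression)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix must have gene rownames and sample colnames")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample identifier(s) in expression matrix")
  if (!all(is.finite(expression))) {
    bad <- which(!is.finite(expression), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value for gene '%s', sample '%s'",
                 gid[bad[1L]], sid[bad[2L]]))
  }
  clinical <- as.data.frame(clinical)
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  clinical$sample_id <- as.character(clinical$sample_id)
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample_id in clinical table")
  bad_t <- !is.finite(clinical$os_time) | clinical$os_time <= 0
  if (any(bad_t))
    stop("os_time must be positive and finite; offending sample(s): ",
         paste(clinical$sample_id[bad_t], collapse = ", "))
  if (!all(clinical$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  if (!identical(sid, clinical$sample_id))
    stop("expression samples and clinical samples must be identical and ",
         "identically ordered")
  if ("chemo_response" %in% names(clinical)) {
    resp <- as.character(clinical$chemo_response)
    bad <- setdiff(unique(resp[!is.na(resp) & resp != ""]),
                   c("CR", "PR", "SD", "PD"))
    if (length(bad))
      stop("unknown chemo_response value(s): ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, expression = expression, clinical = clinical),
            class = "grp_cohort")
}

#' @export
print.grp_cohort <- function(x, ...) {
  cat(sprintf("<grp_cohort> %s: %d genes x %d samples, %d events\n",
              x$name, nrow(x$expression), ncol(x$expression),
              sum(x$clinical$os_event)))
  invisible(x)
}

#' Load a cohort from expression and clinical TSV files
#'
#' The expression file is tab-separated with gene identifiers in the first
#' column and a header row of sample identifiers; the clinical file is
#' tab-separated with at least `sample_id`, `os_time`, `os_event`. Samples
#' are restricted to the intersection of the two files; expression columns
#' are reordered to clinical row order (clinical order is canonical).
#' Dropped samples are reported via warnings.
#'
#' Expression is assumed to be already normalized and log2-transformed;
#' the loader validates finiteness but never rescales. Gene identifiers are
#' opaque strings (no alias mapping, no probe collapsing).
#'
#' @param expression_path Path to the expression TSV.
#' @param clinical_path Path to the clinical TSV.
#' @param cohort_name Name for the cohort.
#' @return A `grp_cohort`.
#' @export
load_cohort <- function(expression_path, clinical_path, cohort_name) {
  expr_df <- read.delim(expression_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(expr_df) < 2L) stop("expression file has no sample columns")
  gid <- as.character(expr_df[[1L]])
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  mat <- as.matrix(expr_df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gid
  clin <- read.delim(clinical_path, stringsAsFactors = FALSE)
  clin$sample_id <- as.character(clin$sample_id)

  shared <- intersect(clin$sample_id, colnames(mat))
  if (length(shared) < 2L)
    stop("fewer than 2 samples shared between expression and clinical files")
  drop_expr <- setdiff(colnames(mat), shared)
  drop_clin <- setdiff(clin$sample_id, shared)
  for (s in drop_expr)
    warning(sprintf("sample '%s' in expression but not clinical: dropped", s),
            call. = FALSE)
  for (s in drop_clin)
    warning(sprintf("sample '%s' in clinical but not expression: dropped", s),
            call. = FALSE)
  clin <- clin[clin$sample_id %in% shared, , drop = FALSE]
  mat <- mat[, clin$sample_id, drop = FALSE]
  cohort(cohort_name, mat, clin)
}

#' Write a cohort to the TSV dialects `load_cohort()` reads
#'
#' @param x A `grp_cohort`.
#' @param expression_path,clinical_path Output paths.
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, expression_path, clinical_path) {
  stopifnot(inherits(x, "grp_cohort"))
  expr_df <- data.frame(gene_id = rownames(x$expression), x$expression,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write.table(expr_df, expression_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$clinical, clinical_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated
#' (the MSigDB interchange format). Within-set duplicates are collapsed with
#' a warning; lines without genes are skipped with a warning; duplicate set
#' names are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of `grp_geneset` objects (fields `name`,
#'   `description`, `members`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    nm <- parts[1L]
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning(sprintf("gene set '%s' has no genes: skipped", nm),
              call. = FALSE)
      next
    }
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': duplicate member genes collapsed", nm),
              call. = FALSE)
      genes <- unique(genes)
    }
    if (nm %in% names(sets))
      stop("duplicate gene set name: ", nm)
    sets[[nm]] <- structure(
      list(name = nm,
           description = if (length(parts) >= 2L) parts[2L] else "",
           members = genes),
      class = "grp_geneset")
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of `grp_geneset` objects (or a named list of character
#'   vectors of member genes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "grp_geneset"))
      paste(c(s$name, s$description, s$members), collapse = "\t")
    else
      paste(c(names(sets)[i], "", s), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
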