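#' Construct an expression study
#'
#' Bundles one study's genes x samples expression matrix with its per-sample
#' phenotype table. Gene ids are canonicalized to upper case; rows sharing a
#' canonical id (multiple probes for one gene) are collapsed to their
#' per-sample arithmetic mean. Samples present in only one of the two inputs
#' are dropped with a warning; the study keeps the intersection.
#'
#' @param mat numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param phenotype data frame with columns `sample_id`, `group`, `status`
#'   (one of `"SLE"`, `"HEALTHY"`, `"UNKNOWN"`) and `sledai` (non-negative
#'   integer or `NA`).
#' @param study_id identifier string.
#' @return object of class `"expression_study"`.
#' @export
expression_study <- function(mat, phenotype, study_id) {
  stopifnot(is.matrix(mat), is.numeric(mat),
            is.character(study_id), length(study_id) == 1L)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (any(is.na(mat))) {
    stop("missing values are not permitted in expression matrices",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate sample ids in matrix", call. = FALSE)
  }
  rownames(mat) <- canonical_gene(rownames(mat))
  if (anyDuplicated(rownames(mat))) {
    mat <- collapse_duplicate_genes(mat)
  }

  need <- c("sample_id", "group", "status", "sledai")
  if (!all(need %in% names(phenotype))) {
    stop("phenotype table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ph <- data.frame(sample_id = as.character(phenotype$sample_id),
                   group = as.character(phenotype$group),
                   status = toupper(as.character(phenotype$status)),
                   sledai = suppressWarnings(as.integer(phenotype$sledai)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ph$sample_id)) {
    stop("duplicate sample ids in phenotype table", call. = FALSE)
  }
  if (!all(ph$status %in% c("SLE", "HEALTHY", "UNKNOWN"))) {
    stop("status must be SLE, HEALTHY or UNKNOWN", call. = FALSE)
  }
  if (any(!is.na(ph$sledai) & ph$sledai < 0L)) {
    stop("sledai must be a non-negative integer", call. = FALSE)
  }

  common <- intersect(colnames(mat), ph$sample_id)
  if (length(common) == 0L) {
    stop("no samples shared between matrix and phenotype table",
         call. = FALSE)
  }
  if (length(common) < ncol(mat)) {
    warning(ncol(mat) - length(common),
            " matrix sample(s) without phenotype dropped", call. = FALSE)
  }
  if (length(common) < nrow(ph)) {
    warning(nrow(ph) - length(common),
            " phenotype sample(s) absent from matrix dropped", call. = FALSE)
  }
  mat <- mat[, common, drop = FALSE]
  ph <- ph[match(common, ph$sample_id), , drop = FALSE]
  rownames(ph) <- NULL
  structure(list(study_id = study_id, matrix = mat, phenotype = ph),
            class = "expression_study")
}

# Average rows that share a canonical gene id; order-independent.
collapse_duplicate_genes <- function(mat) {
  f <- factor(rownames(mat), levels = unique(sort(rownames(mat))))
  out <- rowsum(mat, f) / as.vector(table(f))
  out[order(rownames(out)), , drop = FALSE]
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study '", x$study_id, "': ", nrow(x$matrix), " genes x ",
      ncol(x$matrix), " samples\n", sep = "")
  tab <- table(x$phenotype$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression study from tab-delimited files
#'
#' The matrix file is a TSV whose header row holds sample ids and whose
#' first column (`gene`) holds gene ids; all remaining cells must be
#' numeric. The phenotype file is a TSV with header
#' `sample_id, group, status, sledai` (`sledai` may be empty).
#'
#' @param matrix_path path to the expression TSV.
#' @param phenotype_path path to the phenotype TSV.
#' @param study_id study identifier; defaults to the matrix file name
#'   without extension.
#' @return an `expression_study`.
#' @export
read_expression_study <- function(matrix_path, phenotype_path,
                                  study_id = NULL) {
  if (is.null(study_id)) {
    study_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  }
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L || names(df)[1] != "gene") {
    stop("malformed matrix header: first column must be 'gene'",
         call. = FALSE)
  }
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric value at gene '", genes[bad[1]], "', sample '",
         colnames(vals)[bad[2]], "'", call. = FALSE)
  }
  rownames(num) <- genes
  ph <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  expression_study(num, ph, study_id)
}

#' Write an expression study to tab-delimited files
#'
#' Inverse of [read_expression_study()].
#'
#' @param study an `expression_study`.
#' @param matrix_path,phenotype_path output paths.
#' @return `invisible(NULL)`.
#' @export
write_expression_study <- function(study, matrix_path, phenotype_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$phenotype, phenotype_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(NULL)
}
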