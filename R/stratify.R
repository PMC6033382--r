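#' Project a study onto a meta-signature
#'
#' Restricts the expression matrix to the meta-signature genes present in
#' the study and z-scores each gene across samples (mean 0, sd 1), the
#' representation used for clustering and centroid correlation. Constant
#' genes, whose z-score is undefined, are dropped with a warning. An error
#' is raised when fewer than `min_fraction` of the meta-signature genes are
#' measured in the study, since too sparse a projection is not a meaningful
#' meta-profile.
#'
#' @param study an `expression_study`.
#' @param ms a `meta_signature`.
#' @param min_fraction minimum fraction of meta-signature genes that must
#'   be present, default 0.5.
#' @return numeric matrix (projected genes x samples), z-scored by row.
#' @export
project_study <- function(study, ms, min_fraction = 0.5) {
  stopifnot(inherits(study, "expression_study"),
            inherits(ms, "meta_signature"))
  genes <- metasig_genes(ms)
  present <- intersect(genes, rownames(study$matrix))
  frac <- length(present) / length(genes)
  if (frac < min_fraction) {
    stop(sprintf("only %.0f%% of meta-signature genes present (need %.0f%%)",
                 100 * frac, 100 * min_fraction), call. = FALSE)
  }
  sub <- study$matrix[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from projection",
            call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (sub - rowMeans(sub)) / sds
}

#' Split samples at the first bifurcation of an average-linkage dendrogram
#'
#' Unsupervised hierarchical clustering of samples with pairwise distance
#' `1 - Pearson correlation` over the projected genes and average linkage
#' (UPGMA). The root merge of the dendrogram defines the two sample groups;
#' the group containing the lexically smallest sample id is reported as
#' "left" (a naming convention only, with no semantics).
#'
#' @param projected genes x samples matrix from [project_study()] (>= 2
#'   samples).
#' @return list of class `"stratification"` with `left_ids`, `right_ids`
#'   and the `hclust` object (`linkage`).
#' @export
hcluster_split <- function(projected) {
  stopifnot(is.matrix(projected))
  if (ncol(projected) < 2L) stop("need at least 2 samples", call. = FALSE)
  cors <- stats::cor(projected)
  if (any(is.na(cors))) {
    stop("undefined sample correlation (zero-variance profile)",
         call. = FALSE)
  }
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, k = 2L)
  ids <- colnames(projected)
  anchor <- grp[[min(ids)]]
  structure(list(left_ids = sort(ids[grp == anchor]),
                 right_ids = sort(ids[grp != anchor]),
                 linkage = hc),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("First-bifurcation split: left n=", length(x$left_ids),
      ", right n=", length(x$right_ids), "\n", sep = "")
  invisible(x)
}

#' Test disease enrichment between two stratified groups
#'
#' Examines whether the two first-bifurcation groups differ in disease
#' composition: a two-sided tie-corrected Mann-Whitney U test on status
#' coded 1 (SLE) / 0 (healthy) between the groups, with a two-sided
#' Fisher's exact test on the 2x2 group-by-status table reported alongside
#' as the interpretable cross-check.
#'
#' @param split a `stratification`.
#' @param phenotype phenotype data frame (`sample_id`, `status`) covering
#'   every clustered sample with status `"SLE"` or `"HEALTHY"`.
#' @return list with counts (`healthy_in_left`, `healthy_in_right`,
#'   `total_left`, `total_right`) and p-values (`p_mwu`, `p_fisher`).
#' @export
enrichment_test <- function(split, phenotype) {
  stopifnot(inherits(split, "stratification"))
  if (length(split$left_ids) == 0L || length(split$right_ids) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  status <- stats::setNames(toupper(phenotype$status), phenotype$sample_id)
  all_ids <- c(split$left_ids, split$right_ids)
  if (!all(all_ids %in% names(status))) {
    stop("phenotype missing for some clustered samples", call. = FALSE)
  }
  st <- status[all_ids]
  if (!all(st %in% c("SLE", "HEALTHY"))) {
    stop("every sample must have status SLE or HEALTHY", call. = FALSE)
  }
  code <- as.numeric(st == "SLE")
  in_left <- all_ids %in% split$left_ids
  mw <- mann_whitney_u(code[in_left], code[!in_left])
  tab <- matrix(c(sum(in_left & st == "HEALTHY"),
                  sum(!in_left & st == "HEALTHY"),
                  sum(in_left & st == "SLE"),
                  sum(!in_left & st == "SLE")), nrow = 2L,
                dimnames = list(c("left", "right"), c("HEALTHY", "SLE")))
  list(healthy_in_left = tab["left", "HEALTHY"],
       healthy_in_right = tab["right", "HEALTHY"],
       total_left = sum(in_left), total_right = sum(!in_left),
       p_mwu = mw$p, p_fisher = fisher_exact_2x2(tab))
}

#' Retrospectively stratify a study with a meta-signature
#'
#' Convenience wrapper: project, split at the first bifurcation, and test
#' enrichment of the disease labels.
#'
#' @inheritParams project_study
#' @return list with the `stratification` (`split`) and the enrichment
#'   results (`enrichment`).
#' @export
stratify_study <- function(study, ms, min_fraction = 0.5) {
  pr <- project_study(study, ms, min_fraction)
  split <- hcluster_split(pr)
  list(split = split, enrichment = enrichment_test(split, study$phenotype))
}
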