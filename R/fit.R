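#' Fit a meta-signature model to a collection of training studies
#'
#' The full meta-analysis pipeline in one call, the package's central
#' fitting function:
#'
#' 1. extract a directional signature from every pairwise group comparison
#'    within every training study ([all_pairwise_signatures()]);
#' 2. run the all-versus-all directional similarity search
#'    ([all_vs_all()]) and cluster signatures into connected components of
#'    the significance graph ([cluster_signatures()]);
#' 3. assemble the selected cluster's members into per-gene consensus
#'    records and cut the top-`n` meta-signature ([assemble_metasig()],
#'    [top_n_metasig()]);
#' 4. build the disease centroid reference from the training studies and,
#'    when SLEDAI scores are available, the three disease-activity
#'    centroids ([build_centroid()]).
#'
#' By default the largest signature cluster is assembled; pass `cluster` to
#' select another (cluster membership should always be inspected --
#' phenotype knowledge, not size, identifies the disease cluster in real
#' collections).
#'
#' @param studies list of `expression_study` training studies.
#' @param n meta-signature size, default 100.
#' @param fdr_alpha,max_entries,min_group_size extraction settings, see
#'   [extraction_config()].
#' @param alpha similarity significance level, default 0.01.
#' @param cluster index of the signature cluster to assemble (clusters are
#'   ordered by decreasing size), default 1.
#' @param threshold Spearman threshold stored for prediction, default 0.3.
#' @param build_da build disease-activity centroids; default: yes when any
#'   training sample has a SLEDAI score.
#' @return object of class `"metasig_fit"` with components `signatures`,
#'   `similarities`, `clusters`, `cluster_index`, `records`, `metasig`,
#'   `centroid`, `da_centroids`, `threshold`, `call`.
#' @seealso [predict.metasig_fit()], [stratify_study()], [classify_study()]
#' @export
metasig_fit <- function(studies, n = 100L, fdr_alpha = 0.05,
                        max_entries = 500L, min_group_size = 3L,
                        alpha = 0.01, cluster = 1L, threshold = 0.3,
                        build_da = NULL) {
  stopifnot(length(studies) >= 1L,
            all(vapply(studies, inherits, logical(1), "expression_study")))
  cfg <- extraction_config(fdr_alpha, max_entries, min_group_size)
  sigs <- unlist(lapply(studies, all_pairwise_signatures, cfg = cfg),
                 recursive = FALSE)
  sigs <- Filter(is_valid_signature, sigs)
  if (length(sigs) < 2L) {
    stop("fewer than 2 valid signatures extracted; nothing to cluster",
         call. = FALSE)
  }
  sims <- all_vs_all(sigs, alpha)
  clusters <- cluster_signatures(sims)
  if (length(clusters) < cluster) {
    stop("no signature cluster at index ", cluster, call. = FALSE)
  }
  members <- clusters[[cluster]]$members
  member_sigs <- sigs[vapply(sigs, function(s) s$signature_id, "") %in%
                        members]
  records <- assemble_metasig(member_sigs)
  ms <- top_n_metasig(records, n, source_cluster = paste0("cluster", cluster))

  if (is.null(build_da)) {
    build_da <- any(vapply(studies, function(st)
      any(!is.na(st$phenotype$sledai)), logical(1)))
  }
  centroid <- build_centroid(studies, ms, status = "SLE")
  da_centroids <- NULL
  if (isTRUE(build_da)) {
    da_centroids <- lapply(1:3, function(b)
      build_centroid(studies, ms, bin = b))
  }
  structure(list(signatures = sigs, similarities = sims,
                 clusters = clusters, cluster_index = as.integer(cluster),
                 records = records, metasig = ms, centroid = centroid,
                 da_centroids = da_centroids, threshold = threshold,
                 call = match.call()),
            class = "metasig_fit")
}

#' @export
print.metasig_fit <- function(x, ...) {
  cat("Meta-signature model\n")
  cat("  signatures: ", length(x$signatures), " from ",
      length(unique(vapply(x$signatures, function(s) s$study_id, ""))),
      " studies; ", length(x$clusters), " cluster(s)\n", sep = "")
  cat("  assembled cluster ", x$cluster_index, " (",
      length(x$clusters[[x$cluster_index]]$members), " members)\n",
      sep = "")
  print(x$metasig)
  cat("  prediction threshold: rho >= ", x$threshold, "\n", sep = "")
  if (!is.null(x$da_centroids)) {
    cat("  disease-activity centroids: S1/S2/S3\n")
  }
  invisible(x)
}

#' @export
summary.metasig_fit <- function(object, ...) {
  sizes <- vapply(object$clusters, function(cl) length(cl$members),
                  integer(1))
  structure(list(n_signatures = length(object$signatures),
                 n_significant_pairs = sum(object$similarities$significant),
                 cluster_sizes = sizes,
                 cluster_index = object$cluster_index,
                 metasig = object$metasig,
                 top = utils::head(object$metasig$records, 10L),
                 centroid = object$centroid,
                 threshold = object$threshold),
            class = "summary.metasig_fit")
}

#' @export
print.summary.metasig_fit <- function(x, ...) {
  cat("Meta-signature model summary\n")
  cat("  ", x$n_signatures, " signatures, ", x$n_significant_pairs,
      " significant similarity pairs\n", sep = "")
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  print(x$metasig)
  cat("  top-ranked genes:\n")
  print(x$top, row.names = FALSE)
  print(x$centroid)
  invisible(x)
}

#' Centroid coefficients of a fitted meta-signature model
#'
#' The disease centroid's per-gene reference values (study-standardized
#' units), the fixed side of the rank correlation used for prediction.
#'
#' @param object a `metasig_fit`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.metasig_fit <- function(object, ...) {
  object$centroid$values
}

#' Classify the samples of a new study with a fitted meta-signature model
#'
#' Projects the new study onto the meta-signature (per-gene z-score across
#' the new study's samples), correlates each sample with the disease
#' centroid (Spearman) and calls disease at `rho >= threshold`
#' (inclusive). Disease-activity bins are assigned by maximal correlation
#' with the three activity centroids when available.
#'
#' @param object a `metasig_fit`.
#' @param newdata an `expression_study`.
#' @param threshold correlation threshold; defaults to the fitted one.
#' @param da add disease-activity calls (default: when activity centroids
#'   exist).
#' @param min_shared minimum shared genes per sample, default 10.
#' @param min_fraction minimum meta-signature coverage of the study,
#'   default 0.5.
#' @param ... unused.
#' @return data frame from [classify_study()].
#' @export
predict.metasig_fit <- function(object, newdata, threshold = NULL,
                                da = NULL, min_shared = 10L,
                                min_fraction = 0.5, ...) {
  stopifnot(inherits(newdata, "expression_study"))
  if (is.null(threshold)) threshold <- object$threshold
  if (is.null(da)) da <- !is.null(object$da_centroids)
  classify_study(newdata, object$metasig, object$centroid,
                 da_centroids = if (isTRUE(da)) object$da_centroids,
                 threshold = threshold, min_shared = min_shared,
                 min_fraction = min_fraction)
}

#' Plot the direction-concordance map of a fitted meta-signature
#'
#' Displays meta-signature genes (rows, rank order) against the member
#' signatures of the assembled cluster (columns); cell values are the
#' member's direction for that gene weighted by its scaled confidence
#' (red up, blue down, white absent).
#'
#' @param x a `metasig_fit`.
#' @param max_genes cap on displayed genes, default 100.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.metasig_fit <- function(x, max_genes = 100L, ...) {
  members <- x$clusters[[x$cluster_index]]$members
  member_sigs <- x$signatures[vapply(x$signatures,
                                     function(s) s$signature_id, "") %in%
                                members]
  genes <- utils::head(metasig_genes(x$metasig), max_genes)
  m <- matrix(0, nrow = length(genes), ncol = length(member_sigs),
              dimnames = list(genes,
                              vapply(member_sigs,
                                     function(s) s$signature_id, "")))
  for (j in seq_along(member_sigs)) {
    tb <- sig_table(member_sigs[[j]])
    idx <- match(genes, tb$gene)
    hit <- !is.na(idx)
    m[hit, j] <- tb$dir[idx[hit]] * tb$w[idx[hit]]
  }
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(63)
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, zlim = c(-1, 1), axes = FALSE,
                  xlab = "member signatures",
                  ylab = "meta-signature genes (rank order)", ...)
  graphics::box()
  invisible(m)
}
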