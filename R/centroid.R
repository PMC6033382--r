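#' Map SLEDAI scores to disease-activity bins
#'
#' Standard clinical binning: S1 for SLEDAI 0-2 (low activity), S2 for
#' 3-7 (moderate), S3 above 7 (high).
#'
#' @param sledai integer vector of SLEDAI scores (NA allowed).
#' @return integer bin 1/2/3 (NA where sledai is NA).
#' @export
sledai_bin <- function(sledai) {
  out <- ifelse(is.na(sledai), NA_integer_,
                ifelse(sledai <= 2L, 1L, ifelse(sledai <= 7L, 2L, 3L)))
  as.integer(out)
}

#' Standardize a study's meta-signature genes against its control baseline
#'
#' Expression of each gene is centered at the mean of the study's healthy
#' control samples and scaled by the gene's standard deviation across all
#' samples, yielding profiles in "change relative to the normal baseline"
#' units -- the representation in which a directional reference signature
#' is meaningful. Centering at the overall cohort mean instead would
#' subtract most of the disease signal out of a case-dominated cohort and
#' silently re-center any fixed correlation threshold. When a study has no
#' healthy samples the cohort mean is the only available baseline and is
#' used with a warning. Constant genes are dropped with a warning.
#'
#' @param study an `expression_study`.
#' @param genes character vector of genes to standardize (those absent
#'   from the study are skipped).
#' @return numeric matrix (genes x samples) of baseline-referenced values.
#' @export
baseline_standardize <- function(study, genes) {
  stopifnot(inherits(study, "expression_study"))
  present <- intersect(genes, rownames(study$matrix))
  if (length(present) == 0L) {
    stop("none of the requested genes are measured in study '",
         study$study_id, "'", call. = FALSE)
  }
  sub <- study$matrix[present, , drop = FALSE]
  healthy <- study$phenotype$sample_id[study$phenotype$status == "HEALTHY"]
  if (length(healthy) > 0L) {
    center <- rowMeans(sub[, healthy, drop = FALSE])
  } else {
    warning("study '", study$study_id,
            "' has no healthy samples; centering at cohort mean",
            call. = FALSE)
    center <- rowMeans(sub)
  }
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped", call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    center <- center[sds > 0]
    sds <- sds[sds > 0]
  }
  (sub - center) / sds
}

#' Build a centroid reference signature from training studies
#'
#' Within each training study the meta-signature genes are standardized
#' against the study's healthy-control baseline (see
#' [baseline_standardize()]; this removes study scale and offset), then
#' averaged over the selected samples -- those with disease status
#' `"SLE"`, or those falling in a given disease-activity bin. The centroid
#' value of a gene is the unweighted mean of these per-study means over the
#' studies measuring the gene, so every study contributes equally
#' regardless of its size. Genes measured by no study are omitted.
#'
#' @param training list of `expression_study` objects.
#' @param ms a `meta_signature`.
#' @param status select samples by disease status (default `"SLE"`);
#'   ignored when `bin` is given.
#' @param bin optional disease-activity bin (1, 2 or 3); selects SLE
#'   samples whose SLEDAI falls in that bin.
#' @param tag label stored on the centroid; defaults to `status` or
#'   `"DA<bin>"`.
#' @return object of class `"reference_centroid"`: list with `tag`,
#'   `values` (named numeric), `n_samples_used`, `n_studies_used`.
#' @export
build_centroid <- function(training, ms, status = "SLE", bin = NULL,
                           tag = NULL) {
  stopifnot(length(training) >= 1L, inherits(ms, "meta_signature"))
  if (is.null(tag)) tag <- if (is.null(bin)) status else paste0("DA", bin)
  genes <- metasig_genes(ms)
  sums <- stats::setNames(numeric(length(genes)), genes)
  nstud <- stats::setNames(integer(length(genes)), genes)
  n_samples <- 0L
  n_studies <- 0L
  for (study in training) {
    ph <- study$phenotype
    sel <- if (is.null(bin)) {
      ph$status == status
    } else {
      ph$status == "SLE" & !is.na(ph$sledai) & sledai_bin(ph$sledai) == bin
    }
    if (!any(sel)) next
    if (length(intersect(genes, rownames(study$matrix))) == 0L) next
    z <- baseline_standardize(study, genes)
    if (nrow(z) == 0L) next
    m <- rowMeans(z[, ph$sample_id[sel], drop = FALSE])
    sums[names(m)] <- sums[names(m)] + m
    nstud[names(m)] <- nstud[names(m)] + 1L
    n_samples <- n_samples + sum(sel)
    n_studies <- n_studies + 1L
  }
  if (n_samples == 0L) {
    stop("no samples matched the centroid selector", call. = FALSE)
  }
  keep <- nstud > 0L
  structure(list(tag = tag, values = sums[keep] / nstud[keep],
                 n_samples_used = n_samples, n_studies_used = n_studies),
            class = "reference_centroid")
}

#' @export
print.reference_centroid <- function(x, ...) {
  cat("Reference centroid '", x$tag, "': ", length(x$values), " genes from ",
      x$n_samples_used, " samples in ", x$n_studies_used, " studies\n",
      sep = "")
  invisible(x)
}

#' Classify one sample profile against a centroid
#'
#' Computes the Spearman rank correlation between the centroid and the
#' sample over their shared genes and calls the sample diseased when the
#' correlation reaches the threshold -- the boundary is inclusive
#' (`rho >= threshold` is called `"SLE"`).
#'
#' @param profile named numeric vector, the sample's values over
#'   meta-signature genes.
#' @param centroid a `reference_centroid`.
#' @param threshold correlation threshold in (-1, 1), default 0.3.
#' @param min_shared minimum number of shared genes required, default 10.
#' @return list with `rho` and `call` (`"SLE"`/`"HEALTHY"`).
#' @export
predict_sample <- function(profile, centroid, threshold = 0.3,
                           min_shared = 10L) {
  stopifnot(inherits(centroid, "reference_centroid"),
            threshold > -1, threshold < 1)
  shared <- intersect(names(profile), names(centroid$values))
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " genes shared with centroid (need ",
         min_shared, ")", call. = FALSE)
  }
  rho <- spearman_rho(centroid$values[shared], profile[shared])
  # small epsilon keeps the boundary inclusive under floating-point error
  # (rank arithmetic can return e.g. 0.3 - 7e-17 for an exact 0.3)
  list(rho = rho,
       call = if (rho >= threshold - 1e-9) "SLE" else "HEALTHY")
}

#' Assign a disease-activity bin by maximal centroid correlation
#'
#' Correlates the sample with the three disease-activity centroids and
#' calls the bin with the highest Spearman correlation; exact ties break
#' toward the lower-severity bin (a conservative clinical default).
#'
#' @param profile named numeric vector over meta-signature genes.
#' @param centroids list of three `reference_centroid` objects in severity
#'   order (S1, S2, S3).
#' @param min_shared minimum shared genes per centroid, default 10.
#' @return list with `da_rhos` (length-3 numeric) and `da_call`
#'   (`"S1"`/`"S2"`/`"S3"`).
#' @export
predict_da <- function(profile, centroids, min_shared = 10L) {
  if (length(centroids) != 3L ||
      !all(vapply(centroids, inherits, logical(1), "reference_centroid"))) {
    stop("need three disease-activity centroids", call. = FALSE)
  }
  rhos <- vapply(centroids, function(ct) {
    shared <- intersect(names(profile), names(ct$values))
    if (length(shared) < min_shared) {
      stop("only ", length(shared), " genes shared with centroid '",
           ct$tag, "'", call. = FALSE)
    }
    spearman_rho(ct$values[shared], profile[shared])
  }, numeric(1))
  # which.max returns the first maximum: ties resolve to lower severity
  list(da_rhos = stats::setNames(rhos, c("S1", "S2", "S3")),
       da_call = c("S1", "S2", "S3")[which.max(rhos)])
}

#' Classify every sample of a test study
#'
#' Standardizes the test study's meta-signature genes against its
#' healthy-control baseline (mirroring the centroid construction, see
#' [baseline_standardize()]) and classifies each sample against the
#' disease centroid, optionally adding disease-activity calls. The
#' per-sample call uses only the sample's own profile and the reference;
#' sample labels enter only through the study-level baseline.
#'
#' @param study an `expression_study`.
#' @param ms a `meta_signature`.
#' @param centroid disease `reference_centroid`.
#' @param da_centroids optional list of three disease-activity centroids.
#' @param threshold correlation threshold, default 0.3 (inclusive).
#' @param min_shared minimum shared genes per sample, default 10.
#' @param min_fraction minimum meta-signature coverage of the study,
#'   default 0.5.
#' @return data frame with `sample_id`, `rho`, `call` and, when
#'   disease-activity centroids are given, `rho_da1`..`rho_da3`, `da_call`.
#' @export
classify_study <- function(study, ms, centroid, da_centroids = NULL,
                           threshold = 0.3, min_shared = 10L,
                           min_fraction = 0.5) {
  genes <- metasig_genes(ms)
  frac <- length(intersect(genes, rownames(study$matrix))) / length(genes)
  if (frac < min_fraction) {
    stop(sprintf("only %.0f%% of meta-signature genes present (need %.0f%%)",
                 100 * frac, 100 * min_fraction), call. = FALSE)
  }
  pr <- baseline_standardize(study, genes)
  res <- lapply(colnames(pr), function(sid) {
    prof <- pr[, sid]
    p <- predict_sample(prof, centroid, threshold, min_shared)
    row <- data.frame(sample_id = sid, rho = p$rho, call = p$call,
                      stringsAsFactors = FALSE)
    if (!is.null(da_centroids)) {
      d <- predict_da(prof, da_centroids, min_shared)
      row$rho_da1 <- d$da_rhos[[1]]
      row$rho_da2 <- d$da_rhos[[2]]
      row$rho_da3 <- d$da_rhos[[3]]
      row$da_call <- d$da_call
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
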