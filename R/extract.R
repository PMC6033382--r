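#' Configuration for signature extraction
#'
#' @param fdr_alpha Benjamini-Hochberg FDR threshold for including a gene,
#'   in (0, 1). Default 0.05.
#' @param max_entries cap on signature size; the most confident genes are
#'   kept. Default 500, which reproduces the several-hundred-gene scale of
#'   typical microarray contrast signatures.
#' @param min_group_size smallest group size eligible for a contrast
#'   (>= 2). Default 3.
#' @return object of class `"extraction_config"`.
#' @export
extraction_config <- function(fdr_alpha = 0.05, max_entries = 500L,
                              min_group_size = 3L) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, max_entries >= 1L,
            min_group_size >= 2L)
  structure(list(test = "ranksum", fdr_alpha = fdr_alpha,
                 max_entries = as.integer(max_entries),
                 min_group_size = as.integer(min_group_size)),
            class = "extraction_config")
}

# Row-wise two-sided Wilcoxon rank-sum p-values for group b vs group a.
# Exact null distribution when a row has no ties and the smaller group has
# at most 50 samples (the switchover convention of stats::wilcox.test);
# exact permutation null by enumeration for tied rows when the group
# split is small enough to enumerate; tie-corrected normal approximation
# with continuity correction otherwise.
# The exact path matters: with a small control group the normal
# approximation floors attainable p-values well above what multiple-testing
# correction over a genome-scale universe can accept.
row_ranksum_p <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  n <- na + nb
  ranks <- t(apply(sub, 1L, rank))
  w_b <- rowSums(ranks[, (na + 1L):n, drop = FALSE])
  u_b <- w_b - nb * (nb + 1) / 2
  # sum(t^3 - t) over tie groups, from the rank variance identity:
  # sum (r_i - (n+1)/2)^2 = (n^3 - n)/12 - sum(t^3 - t)/12
  ss <- rowSums((ranks - (n + 1) / 2)^2)
  tie_term <- pmax(0, (n^3 - n) - 12 * ss)
  tied <- tie_term > 1e-8

  p <- numeric(nrow(sub))
  use_exact <- !tied & (min(na, nb) <= 50L)
  if (any(use_exact)) {
    u <- u_b[use_exact]
    hi <- u > na * nb / 2
    pe <- ifelse(hi,
                 2 * stats::pwilcox(u - 1, nb, na, lower.tail = FALSE),
                 2 * stats::pwilcox(u, nb, na))
    p[use_exact] <- pmin(1, pe)
  }
  # tied rows small enough to enumerate get the exact permutation null
  use_enum <- tied & (choose(n, nb) <= 2000)
  if (any(use_enum)) {
    combs <- utils::combn(n, nb)
    for (i in which(use_enum)) {
      wdist <- colSums(matrix(ranks[i, combs], nrow = nb))
      w <- w_b[i]
      p[i] <- min(1, 2 * min(mean(wdist <= w), mean(wdist >= w)))
    }
  }
  norm_rows <- which(!(use_exact | use_enum))
  if (length(norm_rows) > 0L) {
    sigma <- sqrt(na * nb / 12 *
                    ((n + 1) - tie_term[norm_rows] / (n * (n - 1))))
    z <- u_b[norm_rows] - na * nb / 2
    z <- (z - sign(z) * 0.5) / sigma
    pn <- pmin(1, 2 * stats::pnorm(-abs(z)))
    pn[sigma == 0] <- 1  # fully degenerate row
    p[norm_rows] <- pn
  }
  p
}

#' Extract a directional signature from one two-group contrast
#'
#' For every gene a two-sided Wilcoxon rank-sum test of `group_b` (case)
#' versus `group_a` (baseline) is computed; genes passing the
#' Benjamini-Hochberg FDR threshold enter the signature with direction
#' `sign(median_b - median_a)` and confidence `-log10(p)` (p floored at
#' 1e-300). Genes whose group medians are equal are excluded even if the
#' test is significant, since no direction can be assigned. The signature is
#' truncated to the most confident `max_entries` genes.
#'
#' @param study an `expression_study`.
#' @param group_a baseline group label.
#' @param group_b case group label (directions are relative to this group).
#' @param cfg an [extraction_config()].
#' @return a `gene_signature` with `universe_size` = number of genes tested.
#'   A contrast where no gene passes yields a zero-entry (invalid)
#'   signature with the universe intact.
#' @export
extract_signature <- function(study, group_a, group_b,
                              cfg = extraction_config()) {
  stopifnot(inherits(study, "expression_study"),
            inherits(cfg, "extraction_config"))
  groups <- study$phenotype$group
  for (g in c(group_a, group_b)) {
    if (!g %in% groups) stop("no such group: '", g, "'", call. = FALSE)
    if (sum(groups == g) < cfg$min_group_size) {
      stop("group '", g, "' has fewer than ", cfg$min_group_size,
           " samples", call. = FALSE)
    }
  }
  idx_a <- which(groups == group_a)
  idx_b <- which(groups == group_b)
  mat <- study$matrix
  p <- row_ranksum_p(mat, idx_a, idx_b)
  med_a <- apply(mat[, idx_a, drop = FALSE], 1L, stats::median)
  med_b <- apply(mat[, idx_b, drop = FALSE], 1L, stats::median)
  direction <- sign(med_b - med_a)
  padj <- stats::p.adjust(p, method = "BH")
  keep <- which(padj <= cfg$fdr_alpha & direction != 0)
  entries <- NULL
  if (length(keep) > 0L) {
    conf <- -log10(pmax(p[keep], 1e-300))
    entries <- data.frame(gene = rownames(mat)[keep],
                          direction = as.integer(direction[keep]),
                          confidence = conf, stringsAsFactors = FALSE)
    entries <- entries[order(-entries$confidence, entries$gene), ,
                       drop = FALSE]
    entries <- utils::head(entries, cfg$max_entries)
  }
  gene_signature(paste(study$study_id, group_a, group_b, sep = "|"),
                 study$study_id, c(group_a, group_b), entries, nrow(mat))
}

# Status of a group: HEALTHY only if every member sample is HEALTHY.
group_status <- function(study, group) {
  st <- study$phenotype$status[study$phenotype$group == group]
  if (all(st == "HEALTHY")) "HEALTHY" else if (any(st == "SLE")) "SLE"
  else "UNKNOWN"
}

#' Extract signatures from all pairwise group comparisons
#'
#' One signature per unordered pair of eligible groups (those with at least
#' `min_group_size` samples), so `choose(k, 2)` signatures for `k` eligible
#' groups. Contrast orientation is deterministic: a group whose samples are
#' all healthy is always the baseline; otherwise the lexically later group
#' label is the case. This keeps "up" meaning "up in the disease-like
#' group" across studies.
#'
#' @param study an `expression_study`.
#' @param cfg an [extraction_config()].
#' @return list of `gene_signature` objects.
#' @export
all_pairwise_signatures <- function(study, cfg = extraction_config()) {
  stopifnot(inherits(study, "expression_study"))
  tab <- table(study$phenotype$group)
  eligible <- sort(names(tab)[tab >= cfg$min_group_size])
  if (length(eligible) < 2L) {
    stop("need at least 2 groups with >= ", cfg$min_group_size,
         " samples", call. = FALSE)
  }
  pairs <- utils::combn(eligible, 2L, simplify = FALSE)
  lapply(pairs, function(pr) {
    st <- c(group_status(study, pr[1]), group_status(study, pr[2]))
    if (st[2] == "HEALTHY" && st[1] != "HEALTHY") pr <- rev(pr)
    # labels are sorted, so pr[1] is lexically earlier = baseline by default
    extract_signature(study, pr[1], pr[2], cfg)
  })
}
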