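# Independent brute-force oracles used to verify the package's statistics.
# These deliberately avoid the code paths they check.

# Two-sided rank-sum p by enumerating every assignment of the pooled values.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  nb <- length(b)
  r <- rank(pooled)
  combs <- utils::combn(n, nb)
  wdist <- colSums(matrix(r[combs], nrow = nb))
  w <- sum(r[(length(a) + 1):n])
  min(1, 2 * min(mean(wdist <= w), mean(wdist >= w)))
}

# Mann-Whitney U for the first sample by direct pair counting.
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Spearman rho as Pearson correlation of mid-ranks, from first principles.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Two-sided Fisher exact p by full enumeration over tables with fixed
# margins (point-probability method, with the customary 1e-7 slack).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1))
  obs <- exp(lchoose(r1, tab[1, 1]) + lchoose(r2, tab[2, 1]) -
               lchoose(N, c1))
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# AUC by exhaustive positive/negative pair comparison.
oracle_auc <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# One-sided binomial upper tail by direct summation.
oracle_binom_tail <- function(k, n) {
  if (k > n) return(0)
  sum(choose(n, k:n)) / 2^n
}

# Hypergeometric upper tail P(X >= k) by direct summation.
oracle_hyper_tail <- function(k, K, N, nd) {
  hi <- min(K, nd)
  if (k > hi) return(0)
  ii <- max(0, k):hi
  sum(exp(lchoose(K, ii) + lchoose(N - K, nd - ii) - lchoose(N, nd)))
}

# Connected components by naive closure over an edge list.
oracle_components <- function(nodes, edges_a, edges_b) {
  comp <- lapply(nodes, identity)
  names(comp) <- nodes
  labels <- stats::setNames(nodes, nodes)
  repeat {
    changed <- FALSE
    for (k in seq_along(edges_a)) {
      la <- labels[[edges_a[k]]]; lb <- labels[[edges_b[k]]]
      if (la != lb) {
        keep <- min(la, lb)
        labels[labels == la | labels == lb] <- keep
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(nodes, labels), sort))
}

# Brute-force UPGMA: O(n^3) agglomeration, returning the two member sets
# of the final merge (the first bifurcation).
oracle_upgma_split <- function(D) {
  labs <- rownames(D)
  members <- as.list(labs)
  sizes <- rep(1L, length(labs))
  d <- D
  diag(d) <- Inf
  while (length(members) > 2L) {
    idx <- which(d == min(d), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    d[i, ] <- newrow; d[, i] <- newrow; d[i, i] <- Inf
    members <- members[-j]; sizes <- sizes[-j]
    d <- d[-j, -j, drop = FALSE]
  }
  lapply(members, sort)
}

# Small builders -------------------------------------------------------

make_sig <- function(id, genes, dirs, confs, universe = 1000L,
                     study = "studyX", contrast = c("a", "b")) {
  gene_signature(id, study, contrast,
                 data.frame(gene = genes, direction = dirs,
                            confidence = confs, stringsAsFactors = FALSE),
                 universe)
}

make_study <- function(mat, groups, status = NULL, sledai = NULL,
                       id = "study1") {
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("smp%02d", seq_len(ncol(mat)))
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("G%03d", seq_len(nrow(mat)))
  }
  if (is.null(status)) {
    status <- ifelse(groups == "healthy", "HEALTHY", "SLE")
  }
  if (is.null(sledai)) sledai <- rep(NA_integer_, ncol(mat))
  expression_study(mat, data.frame(sample_id = colnames(mat),
                                   group = groups, status = status,
                                   sledai = sledai,
                                   stringsAsFactors = FALSE), id)
}

# A meta-signature object built directly from known genes/directions,
# bypassing the assembly pipeline (for tests that target later stages).
ms_from_genes <- function(genes, dirs) {
  rec <- data.frame(rank = seq_along(genes), gene = genes,
                    recurrence = 2L,
                    n_up = as.integer(dirs == 1L) * 2L,
                    n_down = as.integer(dirs == -1L) * 2L,
                    concordance = 1,
                    consensus_direction = as.integer(dirs),
                    mean_confidence = 1,
                    stringsAsFactors = FALSE)
  structure(list(records = rec, n = length(genes),
                 source_cluster = NA_character_),
            class = "meta_signature")
}
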