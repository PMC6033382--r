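#' Directional similarity of two signatures
#'
#' Compares two signatures on the three ingredients a signature carries:
#' gene names, expression directions, and confidence levels. Over the
#' shared genes `O`:
#' * `n_concordant` / `n_discordant` count genes with equal / opposite
#'   directions;
#' * `weighted_score = sum over O of d_a * d_b * min(w_a, w_b)` where each
#'   `w` is the entry confidence scaled by its signature's maximum
#'   confidence (so `w` is in (0, 1]);
#' * `p_concordance` is the one-sided binomial tail
#'   `P(X >= n_concordant | n_overlap, 1/2)` -- direction agreement beyond
#'   coin-flipping;
#' * `p_overlap` is the hypergeometric upper tail of observing at least
#'   `n_overlap` shared genes given the two signature sizes, drawn from a
#'   universe equal to the smaller of the two tested universes
#'   (conservative).
#'
#' The pair is `significant` when both p-values are at most `alpha` and
#' concordant genes outnumber discordant ones: similarity requires shared
#' identity *and* shared directionality.
#'
#' @param a,b valid `gene_signature` objects.
#' @param alpha significance level, default 0.01.
#' @return object of class `"similarity_result"` (a list with fields
#'   `sig_a`, `sig_b`, `n_overlap`, `n_concordant`, `n_discordant`,
#'   `weighted_score`, `p_concordance`, `p_overlap`, `significant`).
#' @export
signature_similarity <- function(a, b, alpha = 0.01) {
  if (!is_valid_signature(a) || !is_valid_signature(b)) {
    stop("both signatures must be valid (>= 1 entry)", call. = FALSE)
  }
  similarity_core(sig_table(a), sig_table(b), alpha)
}

# Precomputed view of a signature used by the pairwise search.
sig_table <- function(sig) {
  conf <- sig$entries$confidence
  mx <- max(conf)
  list(id = sig$signature_id,
       gene = sig$entries$gene,
       dir = sig$entries$direction,
       w = if (mx > 0) conf / mx else rep(1, length(conf)),
       n = nrow(sig$entries),
       universe = sig$universe_size)
}

similarity_core <- function(ta, tb, alpha) {
  idx <- match(ta$gene, tb$gene)
  hit <- !is.na(idx)
  n_overlap <- sum(hit)
  if (n_overlap > 0L) {
    prod_dir <- ta$dir[hit] * tb$dir[idx[hit]]
    n_conc <- sum(prod_dir == 1L)
    n_disc <- n_overlap - n_conc
    score <- sum(prod_dir * pmin(ta$w[hit], tb$w[idx[hit]]))
    p_conc <- stats::pbinom(n_conc - 1L, n_overlap, 0.5, lower.tail = FALSE)
  } else {
    n_conc <- 0L; n_disc <- 0L; score <- 0; p_conc <- 1
  }
  universe <- min(ta$universe, tb$universe)
  k_a <- min(ta$n, universe)
  k_b <- min(tb$n, universe)
  p_over <- stats::phyper(n_overlap - 1L, k_a, universe - k_a, k_b,
                          lower.tail = FALSE)
  structure(list(sig_a = ta$id, sig_b = tb$id,
                 n_overlap = n_overlap, n_concordant = n_conc,
                 n_discordant = n_disc, weighted_score = score,
                 p_concordance = p_conc, p_overlap = p_over,
                 significant = (p_conc <= alpha && p_over <= alpha &&
                                  n_conc > n_disc)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("Similarity ", x$sig_a, " ~ ", x$sig_b, ": overlap ", x$n_overlap,
      " (", x$n_concordant, " concordant), score ",
      sprintf("%.2f", x$weighted_score), ", p_conc ",
      format(x$p_concordance, digits = 3), ", p_overlap ",
      format(x$p_overlap, digits = 3),
      if (x$significant) " [significant]" else "", "\n", sep = "")
  invisible(x)
}

#' All-versus-all signature similarity search
#'
#' Computes [signature_similarity()] for every unordered pair of
#' signatures; `choose(n, 2)` rows. The result is symmetric: the same
#' fields are obtained regardless of which member of a pair is listed
#' first.
#'
#' @param sigs list of valid `gene_signature` objects (>= 2).
#' @param alpha significance level passed to each comparison.
#' @return data frame with one row per pair and the fields of
#'   `similarity_result`.
#' @export
all_vs_all <- function(sigs, alpha = 0.01) {
  stopifnot(length(sigs) >= 2L)
  if (!all(vapply(sigs, is_valid_signature, logical(1)))) {
    stop("all signatures must be valid (>= 1 entry)", call. = FALSE)
  }
  ids <- vapply(sigs, function(s) s$signature_id, "")
  if (anyDuplicated(ids)) stop("duplicate signature ids", call. = FALSE)
  tabs <- lapply(sigs, sig_table)
  pairs <- utils::combn(length(sigs), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    r <- similarity_core(tabs[[pairs[1, j]]], tabs[[pairs[2, j]]], alpha)
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster signatures by significant similarity
#'
#' Builds the graph whose vertices are signatures and whose edges are the
#' significant pairwise similarities, and returns its connected components
#' of size >= 2 (singletons are omitted). Clusters are ordered by
#' decreasing size (ties broken by first member id) and members are sorted
#' lexically.
#'
#' @param results data frame from [all_vs_all()].
#' @return list of clusters, each a list with `members` (character vector)
#'   and `edges` (the significant rows between members).
#' @export
cluster_signatures <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("sig_a", "sig_b", "significant") %in% names(results)))
  ed <- results[results$significant, , drop = FALSE]
  if (nrow(ed) == 0L) return(list())
  nodes <- sort(unique(c(ed$sig_a, ed$sig_b)))
  comp <- stats::setNames(seq_along(nodes), nodes)
  # union-find with path compression by repeated relabelling
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (k in seq_len(nrow(ed))) {
    ra <- find(match(ed$sig_a[k], nodes))
    rb <- find(match(ed$sig_b[k], nodes))
    if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  groups <- split(nodes, roots)
  clusters <- lapply(groups, function(members) {
    members <- sort(members)
    within <- ed[ed$sig_a %in% members & ed$sig_b %in% members, ,
                 drop = FALSE]
    rownames(within) <- NULL
    list(members = members, edges = within)
  })
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  first <- vapply(clusters, function(cl) cl$members[1], "")
  clusters <- clusters[order(-sizes, first)]
  names(clusters) <- NULL
  clusters
}
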