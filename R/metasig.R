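#' Assemble per-gene consensus records from a signature cluster
#'
#' Pools every gene appearing in at least one member signature and counts,
#' per gene: `recurrence` (how many members contain it), `n_up`/`n_down`
#' (direction votes), `concordance = |n_up - n_down| / recurrence`,
#' the consensus direction `sign(n_up - n_down)`, and the mean confidence
#' over the members containing the gene. Genes with a direction tie
#' (`n_up == n_down`) have no defensible consensus direction and are
#' flagged ineligible for the top-N cut.
#'
#' @param cluster_sigs list of >= 2 valid `gene_signature` members.
#' @return data frame with columns `gene`, `recurrence`, `n_up`, `n_down`,
#'   `concordance`, `consensus_direction`, `mean_confidence`, `eligible`.
#' @export
assemble_metasig <- function(cluster_sigs) {
  if (length(cluster_sigs) < 2L) {
    stop("need at least 2 member signatures", call. = FALSE)
  }
  stopifnot(all(vapply(cluster_sigs, is_valid_signature, logical(1))))
  long <- do.call(rbind, lapply(cluster_sigs, function(s) s$entries))
  genes <- sort(unique(long$gene))
  f <- factor(long$gene, levels = genes)
  n_up <- as.integer(rowsum(as.numeric(long$direction == 1L), f))
  n_down <- as.integer(rowsum(as.numeric(long$direction == -1L), f))
  recurrence <- n_up + n_down
  mean_conf <- as.numeric(rowsum(long$confidence, f)) / recurrence
  out <- data.frame(gene = genes,
                    recurrence = recurrence,
                    n_up = n_up, n_down = n_down,
                    concordance = abs(n_up - n_down) / recurrence,
                    consensus_direction = as.integer(sign(n_up - n_down)),
                    mean_confidence = mean_conf,
                    eligible = n_up != n_down,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cut the top-N consensus meta-signature
#'
#' Ranks eligible records lexicographically by recurrence (descending),
#' concordance (descending), mean confidence (descending) and gene id
#' (ascending -- a determinism tie-break only) and keeps the first `n`.
#' If fewer than `n` genes are eligible, all of them are returned with a
#' warning.
#'
#' @param records data frame from [assemble_metasig()].
#' @param n target meta-signature size, default 100.
#' @param source_cluster optional label of the originating cluster.
#' @return object of class `"meta_signature"`: list with `records` (ranked
#'   data frame, a `rank` column prepended), `n`, `source_cluster`.
#' @export
top_n_metasig <- function(records, n = 100L, source_cluster = NA_character_) {
  stopifnot(is.data.frame(records), n >= 1L)
  el <- records[records$eligible, , drop = FALSE]
  if (nrow(el) == 0L) stop("no eligible records to rank", call. = FALSE)
  ord <- order(-el$recurrence, -el$concordance, -el$mean_confidence, el$gene)
  el <- el[ord, , drop = FALSE]
  if (nrow(el) < n) {
    warning("only ", nrow(el), " eligible genes for a top-", n,
            " meta-signature", call. = FALSE)
  }
  el <- utils::head(el, n)
  el <- cbind(rank = seq_len(nrow(el)), el)
  el$eligible <- NULL
  rownames(el) <- NULL
  structure(list(records = el, n = as.integer(n),
                 source_cluster = source_cluster),
            class = "meta_signature")
}

#' Genes of a meta-signature
#' @param ms a `meta_signature`.
#' @return character vector in rank order.
#' @export
metasig_genes <- function(ms) {
  stopifnot(inherits(ms, "meta_signature"))
  ms$records$gene
}

#' @export
print.meta_signature <- function(x, ...) {
  cat("Meta-signature: ", nrow(x$records), " genes (target n = ", x$n,
      ")\n", sep = "")
  cat("  consensus directions: ", sum(x$records$consensus_direction == 1L),
      " up, ", sum(x$records$consensus_direction == -1L), " down\n",
      sep = "")
  cat("  recurrence range: ", min(x$records$recurrence), "-",
      max(x$records$recurrence), "; fully concordant genes: ",
      sum(x$records$concordance == 1), "\n", sep = "")
  invisible(x)
}

#' Write / read a meta-signature as TSV
#'
#' Columns: rank, gene, direction (up/down), recurrence, n_up, n_down,
#' concordance, mean_confidence.
#'
#' @param ms a `meta_signature`.
#' @param path file path.
#' @return `path` invisibly (write) or a `meta_signature` (read).
#' @export
write_meta_signature <- function(ms, path) {
  stopifnot(inherits(ms, "meta_signature"))
  r <- ms$records
  df <- data.frame(rank = r$rank, gene = r$gene,
                   direction = ifelse(r$consensus_direction == 1L,
                                      "up", "down"),
                   recurrence = r$recurrence, n_up = r$n_up,
                   n_down = r$n_down, concordance = r$concordance,
                   mean_confidence = r$mean_confidence,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_signature
#' @param n target size recorded in the object; defaults to the number of
#'   rows read.
#' @export
read_meta_signature <- function(path, n = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rank", "gene", "direction", "recurrence", "n_up", "n_down",
            "concordance", "mean_confidence")
  if (!all(need %in% names(df))) {
    stop("meta-signature file missing columns", call. = FALSE)
  }
  rec <- data.frame(rank = df$rank, gene = canonical_gene(df$gene),
                    recurrence = df$recurrence, n_up = df$n_up,
                    n_down = df$n_down, concordance = df$concordance,
                    consensus_direction = ifelse(df$direction == "up",
                                                 1L, -1L),
                    mean_confidence = df$mean_confidence,
                    stringsAsFactors = FALSE)
  structure(list(records = rec, n = as.integer(if (is.null(n)) nrow(rec)
                                               else n),
                 source_cluster = NA_character_),
            class = "meta_signature")
}
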