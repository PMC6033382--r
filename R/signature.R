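#' Canonicalize gene symbols
#'
#' Gene identifiers are compared case-insensitively throughout the package:
#' every symbol is upper-cased on ingest so that cross-platform and
#' cross-species joins (e.g. mouse "Tlr7" against human "TLR7") work on a
#' single token space. Symbols must be non-empty and contain no whitespace.
#'
#' @param x character vector of gene symbols.
#' @return upper-cased character vector.
#' @export
canonical_gene <- function(x) {
  x <- as.character(x)
  if (any(is.na(x) | !nzchar(x))) {
    stop("gene symbols must be non-empty", call. = FALSE)
  }
  if (any(grepl("[[:space:]]", x))) {
    bad <- x[grepl("[[:space:]]", x)][1]
    stop("gene symbol contains whitespace: '", bad, "'", call. = FALSE)
  }
  toupper(x)
}

#' Construct a directional gene-expression signature
#'
#' A signature is the result of one two-group contrast within one study: a
#' set of genes, each carrying an expression direction (+1 up in the case
#' group, -1 down) and a confidence score (-log10 of the contrast p-value).
#' `universe_size` records how many genes were tested, which the similarity
#' search needs for its overlap statistics.
#'
#' A signature with zero entries is representable (e.g. a contrast where no
#' gene passed the significance rule) but is flagged invalid; invalid
#' signatures are rejected by the similarity search.
#'
#' @param signature_id unique identifier string.
#' @param study_id identifier of the originating study.
#' @param contrast length-2 character vector `c(baseline, case)`; directions
#'   are expressed relative to `case`.
#' @param entries data frame with columns `gene`, `direction` (+1/-1) and
#'   `confidence` (finite, >= 0). Genes must be unique.
#' @param universe_size positive integer, number of genes tested.
#' @return object of class `"gene_signature"`.
#' @export
gene_signature <- function(signature_id, study_id, contrast, entries,
                           universe_size) {
  stopifnot(is.character(signature_id), length(signature_id) == 1L,
            is.character(study_id), length(study_id) == 1L,
            length(contrast) == 2L)
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- data.frame(gene = character(), direction = integer(),
                          confidence = numeric(), stringsAsFactors = FALSE)
  } else {
    entries <- data.frame(gene = canonical_gene(entries$gene),
                          direction = as.integer(entries$direction),
                          confidence = as.numeric(entries$confidence),
                          stringsAsFactors = FALSE)
    if (!all(entries$direction %in% c(1L, -1L))) {
      stop("signature directions must be +1 or -1", call. = FALSE)
    }
    if (any(!is.finite(entries$confidence)) || any(entries$confidence < 0)) {
      stop("signature confidences must be finite and >= 0", call. = FALSE)
    }
    if (anyDuplicated(entries$gene)) {
      dup <- entries$gene[duplicated(entries$gene)][1]
      stop("duplicate gene in signature: '", dup, "'", call. = FALSE)
    }
    rownames(entries) <- NULL
  }
  universe_size <- as.integer(universe_size)
  if (is.na(universe_size) || universe_size < 1L ||
      universe_size < nrow(entries)) {
    stop("universe_size must be a positive integer >= number of entries",
         call. = FALSE)
  }
  structure(list(signature_id = signature_id,
                 study_id = study_id,
                 contrast = stats::setNames(as.character(contrast),
                                            c("baseline", "case")),
                 entries = entries,
                 universe_size = universe_size),
            class = "gene_signature")
}

#' Is a signature valid (non-empty)?
#' @param sig a `gene_signature`.
#' @return logical.
#' @export
is_valid_signature <- function(sig) {
  inherits(sig, "gene_signature") && nrow(sig$entries) > 0L
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$signature_id, "' (study ", x$study_id, ")\n",
      sep = "")
  cat("  contrast: ", x$contrast[["case"]], " vs ", x$contrast[["baseline"]],
      " (baseline)\n", sep = "")
  cat("  entries: ", nrow(x$entries), " of ", x$universe_size,
      " genes tested (", sum(x$entries$direction == 1L), " up, ",
      sum(x$entries$direction == -1L), " down)\n", sep = "")
  if (!is_valid_signature(x)) cat("  [invalid: no entries]\n")
  invisible(x)
}

#' Write a signature to a tab-delimited file
#'
#' The format is a TSV with header `gene<TAB>direction<TAB>confidence`
#' (direction spelled `up`/`down`), preceded by `#key=value` metadata lines
#' carrying `signature_id`, `study_id`, `baseline`, `case` and
#' `universe_size`. [read_signature()] reads it back losslessly.
#'
#' @param sig a `gene_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  meta <- c(paste0("#signature_id=", sig$signature_id),
            paste0("#study_id=", sig$study_id),
            paste0("#baseline=", sig$contrast[["baseline"]]),
            paste0("#case=", sig$contrast[["case"]]),
            paste0("#universe_size=", sig$universe_size))
  body <- paste("gene", "direction", "confidence", sep = "\t")
  if (nrow(sig$entries) > 0L) {
    body <- c(body, paste(sig$entries$gene,
                          ifelse(sig$entries$direction == 1L, "up", "down"),
                          formatC(sig$entries$confidence, digits = 17,
                                  format = "g"),
                          sep = "\t"))
  }
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' @param path input path.
#' @return a `gene_signature`. Zero-entry files are returned as (invalid)
#'   empty signatures rather than rejected.
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(vals, keys)
  need <- c("signature_id", "study_id", "baseline", "case", "universe_size")
  if (!all(need %in% keys)) {
    stop("signature file missing metadata: ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0L || !identical(strsplit(body[1], "\t")[[1]],
                                       c("gene", "direction", "confidence"))) {
    stop("malformed signature header", call. = FALSE)
  }
  if (length(body) > 1L) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L)) stop("malformed signature row", call. = FALSE)
    gene <- vapply(parts, `[[`, "", 1L)
    dir_tok <- vapply(parts, `[[`, "", 2L)
    if (!all(dir_tok %in% c("up", "down"))) {
      stop("unknown direction token: '",
           dir_tok[!dir_tok %in% c("up", "down")][1], "'", call. = FALSE)
    }
    gene <- canonical_gene(gene)
    if (anyDuplicated(gene)) {
      stop("duplicate gene in signature file: '",
           gene[duplicated(gene)][1], "'", call. = FALSE)
    }
    entries <- data.frame(gene = gene,
                          direction = ifelse(dir_tok == "up", 1L, -1L),
                          confidence = as.numeric(vapply(parts, `[[`, "", 3L)),
                          stringsAsFactors = FALSE)
  } else {
    entries <- NULL
  }
  gene_signature(meta[["signature_id"]], meta[["study_id"]],
                 c(meta[["baseline"]], meta[["case"]]), entries,
                 as.integer(meta[["universe_size"]]))
}

#' Construct a homolog map
#'
#' Maps source gene tokens (e.g. mouse symbols or probeset-derived symbols)
#' to canonical target symbols, possibly many-to-one. Used to translate
#' mouse-model signatures onto the human symbol space before meta-analysis.
#'
#' @param source character vector of source tokens.
#' @param target character vector of target symbols (canonicalized).
#' @return object of class `"homolog_map"`: a data frame with columns
#'   `source` and `target`.
#' @export
homolog_map <- function(source, target) {
  stopifnot(length(source) == length(target), length(source) >= 1L)
  source <- canonical_gene(source)
  target <- canonical_gene(target)
  map <- unique(data.frame(source = source, target = target,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(map$source)) {
    dup <- map$source[duplicated(map$source)][1]
    stop("source token maps to multiple targets: '", dup, "'", call. = FALSE)
  }
  structure(map, class = c("homolog_map", "data.frame"))
}

#' Read a two-column homolog map TSV (header: source, target)
#' @param path input path.
#' @return a `homolog_map`.
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df))) {
    stop("homolog map must have columns 'source' and 'target'", call. = FALSE)
  }
  homolog_map(df$source, df$target)
}

#' Translate a signature through a homolog map
#'
#' Each entry's gene is replaced by its mapped target; entries whose gene has
#' no mapping are dropped and counted (attribute `n_unmapped` on the result).
#' When several sources collapse onto one target, the entry with the highest
#' confidence wins; if the maximum is tied between entries with concordant
#' directions they collapse to a single entry, while a discordant tie drops
#' the gene entirely -- a direction is never fabricated. The universe size
#' after translation is the number of distinct map targets, capped at the
#' original universe (the tested universe cannot grow by renaming).
#'
#' @param sig a `gene_signature`.
#' @param hmap a `homolog_map`.
#' @return a translated `gene_signature` (possibly empty, hence invalid),
#'   with attributes `n_unmapped` and `n_discordant_dropped`.
#' @export
map_homologs <- function(sig, hmap) {
  stopifnot(inherits(sig, "gene_signature"), inherits(hmap, "homolog_map"),
            nrow(hmap) >= 1L)
  e <- sig$entries
  idx <- match(e$gene, hmap$source)
  n_unmapped <- sum(is.na(idx))
  e <- e[!is.na(idx), , drop = FALSE]
  e$gene <- hmap$target[idx[!is.na(idx)]]
  n_discordant <- 0L
  if (nrow(e) > 0L) {
    keep <- lapply(split(e, e$gene), function(g) {
      top <- g[g$confidence == max(g$confidence), , drop = FALSE]
      if (length(unique(top$direction)) > 1L) return(NULL)  # discordant tie
      top[1L, , drop = FALSE]
    })
    n_discordant <- sum(vapply(keep, is.null, logical(1)))
    e <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
    if (is.null(e)) {
      e <- data.frame(gene = character(), direction = integer(),
                      confidence = numeric(), stringsAsFactors = FALSE)
    }
    e <- e[order(e$gene), , drop = FALSE]
    rownames(e) <- NULL
  }
  universe <- min(sig$universe_size, length(unique(hmap$target)))
  universe <- max(universe, nrow(e), 1L)
  out <- gene_signature(sig$signature_id, sig$study_id, sig$contrast, e,
                        universe)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_discordant_dropped") <- n_discordant
  out
}
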