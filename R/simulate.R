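#' Configuration for the synthetic multi-study cohort generator
#'
#' The generator emulates the structure of a multi-study blood
#' transcriptomics meta-analysis: several independent studies measuring
#' overlapping but not identical gene sets (per-study dropout standing in
#' for platform differences), study-specific per-gene offsets (scale
#' heterogeneity), a healthy group plus three disease groups graded by
#' disease activity, and an embedded ground-truth signature of directional
#' effects.
#'
#' Disease activity acts on the signature in two ways. Every active
#' signature gene is shifted by `direction * effect_size_delta *
#' da_multipliers[bin]`, so effects scale with activity; and each signature
#' gene carries an *onset bin* (drawn from `onset_probs`) and responds only
#' in samples whose activity bin reaches its onset. Genes with onset 1 form
#' the core signature present at any activity; higher-onset genes are
#' recruited progressively as activity rises. This graded-recruitment
#' geometry is what makes activity bins distinguishable by rank
#' correlation: were every gene active in every bin, the three
#' disease-activity centroids would be scalar multiples of one direction
#' vector and therefore rank-indistinguishable.
#'
#' @param n_studies number of studies, default 13.
#' @param n_genes genes per study universe before dropout, default 10000.
#' @param n_signature_genes embedded signature size, default 100.
#' @param frac_up fraction of signature genes up-regulated, default 0.7
#'   (disease signatures of this kind are predominantly up-regulated).
#' @param samples_per_group samples in each of the three disease-activity
#'   groups, default 20.
#' @param frac_sle fraction of diseased samples in a study, default 0.9
#'   (clinical cohorts of this disease are heavily case-dominated); the
#'   healthy group size is derived from it.
#' @param effect_size_delta base effect size in SD units, default 1.5.
#' @param noise_sd per-sample measurement noise SD, default 1.
#' @param dropout_frac fraction of genes absent per study, default 0.1.
#' @param study_shift_sd SD of per-study per-gene offsets, default 0.5.
#' @param da_multipliers effect multipliers for activity bins S1/S2/S3,
#'   default `c(0.5, 1, 1.5)`.
#' @param onset_probs probabilities of a signature gene's onset bin being
#'   S1/S2/S3; the default (equal thirds) gives each activity stratum a
#'   comparable number of newly recruited genes.
#' @param sledai_ranges integer SLEDAI ranges for the three bins, default
#'   `list(c(0, 2), c(3, 7), c(8, 11))`.
#' @param seed RNG seed; the generated collection is a deterministic
#'   function of the full configuration.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_studies = 13L, n_genes = 10000L,
                             n_signature_genes = 100L, frac_up = 0.7,
                             samples_per_group = 20L, frac_sle = 0.9,
                             effect_size_delta = 1.5, noise_sd = 1,
                             dropout_frac = 0.1, study_shift_sd = 0.5,
                             da_multipliers = c(0.5, 1, 1.5),
                             onset_probs = c(1, 1, 1) / 3,
                             sledai_ranges = list(c(0L, 2L), c(3L, 7L),
                                                  c(8L, 11L)),
                             seed = 1L) {
  stopifnot(n_studies >= 1L, n_genes >= 1L,
            n_signature_genes >= 1L, n_signature_genes <= n_genes,
            frac_up >= 0, frac_up <= 1, samples_per_group >= 2L,
            frac_sle > 0, frac_sle < 1, effect_size_delta >= 0,
            noise_sd > 0, dropout_frac >= 0, dropout_frac < 1,
            study_shift_sd >= 0, length(da_multipliers) == 3L,
            length(onset_probs) == 3L, all(onset_probs >= 0),
            sum(onset_probs) > 0, length(sledai_ranges) == 3L)
  structure(list(n_studies = as.integer(n_studies),
                 n_genes = as.integer(n_genes),
                 n_signature_genes = as.integer(n_signature_genes),
                 frac_up = frac_up,
                 samples_per_group = as.integer(samples_per_group),
                 frac_sle = frac_sle,
                 effect_size_delta = effect_size_delta,
                 noise_sd = noise_sd, dropout_frac = dropout_frac,
                 study_shift_sd = study_shift_sd,
                 da_multipliers = da_multipliers,
                 onset_probs = onset_probs / sum(onset_probs),
                 sledai_ranges = sledai_ranges,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a multi-study expression collection with known ground truth
#'
#' Draws a global per-gene baseline `Normal(0, 1)`, embeds a directional
#' signature (directions +1 with probability `frac_up`, onset bins from
#' `onset_probs`), then generates each study with its own per-gene offsets
#' `Normal(0, study_shift_sd)` and a random `dropout_frac` of genes
#' removed. Each study has a healthy group (sized so that diseased samples
#' make up `frac_sle` of the study) and three disease groups
#' `sle_s1`/`sle_s2`/`sle_s3` of `samples_per_group` samples each. A
#' diseased sample draws an integer SLEDAI uniformly within its bin's
#' range; its active signature genes (onset <= bin) are shifted by
#' `direction * effect_size_delta * da_multipliers[bin]` before adding
#' `Normal(0, noise_sd)` noise.
#'
#' The collection is a deterministic function of the configuration
#' (including its seed); the caller's RNG state is left untouched.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `"synthetic_collection"`: list with `studies`
#'   (list of `expression_study`), `truth` (list with `signature`,
#'   `samples`, `retained`) and `config`.
#' @export
simulate_collection <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(cfg$seed)

  genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  sig_genes <- sort(sample(genes, cfg$n_signature_genes))
  directions <- ifelse(stats::runif(cfg$n_signature_genes) < cfg$frac_up,
                       1L, -1L)
  onset <- sample(1:3, cfg$n_signature_genes, replace = TRUE,
                  prob = cfg$onset_probs)
  mu <- stats::setNames(stats::rnorm(cfg$n_genes), genes)
  signature <- data.frame(gene = sig_genes, direction = directions,
                          onset = onset, stringsAsFactors = FALSE)

  out <- vector("list", cfg$n_studies)
  for (s in seq_len(cfg$n_studies)) {
    out[[s]] <- simulate_one_study(cfg, genes, signature, mu,
                                   sprintf("study%02d", s),
                                   cfg$samples_per_group, cfg$frac_sle)
  }
  studies <- lapply(out, `[[`, "study")
  retained <- lapply(out, `[[`, "kept")
  names(retained) <- vapply(studies, function(x) x$study_id, "")
  truth <- list(signature = signature,
                samples = do.call(rbind, lapply(out, `[[`, "truth")),
                retained = retained)
  structure(list(studies = studies, truth = truth, config = cfg,
                 baseline_means = mu),
            class = "synthetic_collection")
}

# One study drawn from the current RNG stream: per-study offsets and
# dropout, then healthy + three activity groups.
simulate_one_study <- function(cfg, genes, signature, mu, study_id,
                               samples_per_group, frac_sle) {
  offsets <- stats::rnorm(length(genes), 0, cfg$study_shift_sd)
  n_drop <- as.integer(floor(cfg$dropout_frac * length(genes)))
  kept <- if (n_drop > 0L) sort(sample(genes, length(genes) - n_drop))
          else genes
  base <- mu[kept] + offsets[match(kept, genes)]
  sig_idx <- match(signature$gene, kept)       # NA where dropped
  have_sig <- !is.na(sig_idx)

  n_healthy <- max(3L, as.integer(round(
    3 * samples_per_group * (1 - frac_sle) / frac_sle)))
  n_tot <- n_healthy + 3L * samples_per_group
  ids <- c(sprintf("%s_h%03d", study_id, seq_len(n_healthy)),
           sprintf("%s_s1_%03d", study_id, seq_len(samples_per_group)),
           sprintf("%s_s2_%03d", study_id, seq_len(samples_per_group)),
           sprintf("%s_s3_%03d", study_id, seq_len(samples_per_group)))
  group <- c(rep("healthy", n_healthy),
             rep(c("sle_s1", "sle_s2", "sle_s3"),
                 each = samples_per_group))
  bin <- c(rep(NA_integer_, n_healthy),
           rep(1:3, each = samples_per_group))
  sledai <- rep(NA_integer_, n_tot)
  mat <- matrix(0, nrow = length(kept), ncol = n_tot,
                dimnames = list(kept, ids))
  for (j in seq_len(n_tot)) {
    val <- base
    if (!is.na(bin[j])) {
      rg <- cfg$sledai_ranges[[bin[j]]]
      sledai[j] <- rg[1] + sample.int(rg[2] - rg[1] + 1L, 1L) - 1L
      active <- have_sig & (signature$onset <= bin[j])
      if (any(active)) {
        val[sig_idx[active]] <- val[sig_idx[active]] +
          signature$direction[active] * cfg$effect_size_delta *
          cfg$da_multipliers[bin[j]]
      }
    }
    mat[, j] <- val + stats::rnorm(length(kept), 0, cfg$noise_sd)
  }
  ph <- data.frame(sample_id = ids, group = group,
                   status = ifelse(is.na(bin), "HEALTHY", "SLE"),
                   sledai = sledai, stringsAsFactors = FALSE)
  list(study = expression_study(mat, ph, study_id), kept = kept,
       truth = data.frame(study_id = study_id, sample_id = ids,
                          status = ph$status, bin = bin, sledai = sledai,
                          stringsAsFactors = FALSE))
}

#' Simulate an additional cohort sharing a collection's ground truth
#'
#' Generates a new study from the same embedded signature and per-gene
#' baselines as an existing collection (with fresh study offsets, dropout,
#' samples and noise), for use as an independent test or validation
#' cohort whose ground truth matches centroids fitted on the collection.
#'
#' @param collection a `synthetic_collection`.
#' @param samples_per_group samples per disease-activity group; defaults
#'   to the collection's configuration.
#' @param frac_sle diseased fraction of the cohort; defaults to the
#'   collection's configuration.
#' @param study_id identifier for the new cohort.
#' @param seed RNG seed for the cohort draw.
#' @return list with `study` (an `expression_study`) and `truth` (the
#'   per-sample truth table).
#' @export
simulate_cohort <- function(collection, samples_per_group = NULL,
                            frac_sle = NULL, study_id = "cohort01",
                            seed = 1L) {
  stopifnot(inherits(collection, "synthetic_collection"))
  cfg <- collection$config
  if (is.null(samples_per_group)) samples_per_group <- cfg$samples_per_group
  if (is.null(frac_sle)) frac_sle <- cfg$frac_sle
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  genes <- names(collection$baseline_means)
  res <- simulate_one_study(cfg, genes, collection$truth$signature,
                            collection$baseline_means, study_id,
                            as.integer(samples_per_group), frac_sle)
  list(study = res$study, truth = res$truth)
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat("Synthetic collection:", length(x$studies), "studies,",
      x$config$n_genes, "genes,", x$config$n_signature_genes,
      "signature genes (delta =", x$config$effect_size_delta, ")\n")
  invisible(x)
}

#' Split a collection into training and held-out test studies
#'
#' Deterministic split by study index: the last `n_test` studies are
#' withheld as test cohorts and take no part in centroid construction.
#'
#' @param collection a `synthetic_collection`.
#' @param n_test number of held-out studies (default 2), must be smaller
#'   than the collection size.
#' @return list with `train` and `test` (lists of `expression_study`).
#' @export
split_train_test <- function(collection, n_test = 2L) {
  stopifnot(inherits(collection, "synthetic_collection"))
  n <- length(collection$studies)
  n_test <- as.integer(n_test)
  if (n_test < 0L || n_test >= n) {
    stop("n_test must be in [0, number of studies)", call. = FALSE)
  }
  list(train = collection$studies[seq_len(n - n_test)],
       test = if (n_test > 0L) collection$studies[(n - n_test + 1L):n]
              else list())
}

#' Write a synthetic collection to a directory of TSV files
#'
#' Writes one `<study_id>_matrix.tsv` / `<study_id>_phenotype.tsv` pair per
#' study plus `truth_signature.tsv` and `truth_samples.tsv`.
#'
#' @param collection a `synthetic_collection`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "synthetic_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (study in collection$studies) {
    write_expression_study(
      study,
      file.path(dir, paste0(study$study_id, "_matrix.tsv")),
      file.path(dir, paste0(study$study_id, "_phenotype.tsv")))
  }
  utils::write.table(collection$truth$signature,
                     file.path(dir, "truth_signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(collection$truth$samples,
                     file.path(dir, "truth_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}
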