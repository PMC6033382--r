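test_that("baseline standardization centers at the healthy-control mean", {
  mat <- rbind(G1 = c(0, 2, 3, 3), G2 = c(4, 6, 1, 1))
  colnames(mat) <- c("h1", "h2", "d1", "d2")
  st <- make_study(mat, groups = c("healthy", "healthy", "sle", "sle"))
  z <- baseline_standardize(st, c("G1", "G2"))
  expect_equal(unname(z["G1", c("h1", "h2")]),
               c(-1, 1) / stats::sd(mat["G1", ]))
  expect_equal(unname(z["G1", "d1"]), 2 / stats::sd(mat["G1", ]))
  # without healthy controls the cohort mean is the fallback, with warning
  st2 <- make_study(mat, groups = rep("sle", 4))
  expect_warning(z2 <- baseline_standardize(st2, c("G1", "G2")),
                 "no healthy")
  expect_equal(unname(z2["G1", "h1"]), (0 - 2) / stats::sd(mat["G1", ]))
})

test_that("a centroid from identical selected profiles equals that profile", {
  mat <- rbind(G1 = c(0, 2, 3, 3), G2 = c(4, 6, 1, 1), G3 = c(1, 3, 9, 9))
  colnames(mat) <- c("h1", "h2", "d1", "d2")
  st <- make_study(mat, groups = c("healthy", "healthy", "sle", "sle"))
  ms <- ms_from_genes(c("G1", "G2", "G3"), c(1L, -1L, 1L))
  ct <- build_centroid(list(st), ms)
  z <- baseline_standardize(st, c("G1", "G2", "G3"))
  expect_equal(ct$values[c("G1", "G2", "G3")], z[, "d1"])
  expect_equal(ct$n_samples_used, 2L)
  expect_equal(ct$n_studies_used, 1L)
})

test_that("studies contribute to the centroid with equal weight", {
  set.seed(91)
  mk <- function(shift, n_sle, id) {
    mat <- matrix(stats::rnorm(10 * (4 + n_sle)), 10)
    mat[, 5:(4 + n_sle)] <- mat[, 5:(4 + n_sle)] + shift
    rownames(mat) <- sprintf("G%02d", 1:10)
    colnames(mat) <- sprintf("%s_s%02d", id, seq_len(ncol(mat)))
    make_study(mat, groups = c(rep("healthy", 4), rep("sle", n_sle)),
               id = id)
  }
  a <- mk(2, 3, "sA")
  b <- mk(4, 30, "sB")  # ten times the samples must not dominate
  ms <- ms_from_genes(sprintf("G%02d", 1:10), rep(1L, 10))
  ct <- build_centroid(list(a, b), ms)
  ma <- rowMeans(baseline_standardize(a, sprintf("G%02d", 1:10))[, 5:7])
  mb <- rowMeans(baseline_standardize(b, sprintf("G%02d", 1:10))[, 5:34])
  expect_equal(ct$values, (ma + mb) / 2)
  expect_equal(ct$n_studies_used, 2L)
  expect_error(build_centroid(list(a), ms, status = "UNKNOWN"),
               "no samples")
})

test_that("centroid signs recover the embedded directions", {
  coll <- simulate_collection(synthetic_config(
    n_studies = 3L, n_genes = 800L, n_signature_genes = 50L,
    samples_per_group = 12L, seed = 92))
  tru <- coll$truth$signature
  ms <- ms_from_genes(tru$gene, tru$direction)
  ct <- build_centroid(coll$studies, ms)
  present <- intersect(names(ct$values), tru$gene)
  agree <- sign(ct$values[present]) == tru$direction[match(present, tru$gene)]
  expect_gte(mean(agree), 0.95)
})

test_that("sample calls use the inclusive threshold convention", {
  genes <- sprintf("G%02d", 1:5)
  ct <- structure(list(tag = "SLE",
                       values = stats::setNames(c(1, 2, 3, 4, 5), genes),
                       n_samples_used = 10L, n_studies_used = 2L),
                  class = "reference_centroid")
  # identical profile
  r <- predict_sample(ct$values, ct, min_shared = 5L)
  expect_equal(r$rho, 1)
  expect_equal(r$call, "SLE")
  # permutation of ranks with rho exactly 0.3: boundary is called SLE
  prof <- stats::setNames(c(4, 1, 3, 2, 5), genes)
  r <- predict_sample(prof, ct, threshold = 0.3, min_shared = 5L)
  expect_equal(r$rho, 0.3)
  expect_equal(r$call, "SLE")
  # rho 0.2 falls below the threshold
  prof2 <- stats::setNames(c(3, 4, 1, 2, 5), genes)
  r2 <- predict_sample(prof2, ct, threshold = 0.3, min_shared = 5L)
  expect_equal(r2$rho, 0.2)
  expect_equal(r2$call, "HEALTHY")
  # reversed ranks
  r3 <- predict_sample(stats::setNames(5:1, genes), ct, min_shared = 5L)
  expect_equal(r3$rho, -1)
  expect_equal(r3$call, "HEALTHY")
  # shared-gene floor
  expect_error(predict_sample(prof[1:3], ct, min_shared = 5L), "shared")
})

test_that("sample calls are invariant under monotone transforms of expression", {
  set.seed(93)
  genes <- sprintf("G%03d", 1:40)
  ct <- structure(list(tag = "SLE",
                       values = stats::setNames(stats::rnorm(40), genes),
                       n_samples_used = 5L, n_studies_used = 1L),
                  class = "reference_centroid")
  prof <- stats::setNames(stats::rnorm(40), genes)
  r1 <- predict_sample(prof, ct)
  r2 <- predict_sample(exp(prof), ct)
  r3 <- predict_sample(stats::setNames(rank(prof), genes), ct)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$rho, r3$rho)
})

test_that("disease-activity calls take the maximal correlation, ties to lower severity", {
  set.seed(94)
  genes <- sprintf("G%03d", 1:30)
  mk_ct <- function(v, tag) structure(
    list(tag = tag, values = stats::setNames(v, genes),
         n_samples_used = 5L, n_studies_used = 1L),
    class = "reference_centroid")
  v3 <- stats::rnorm(30)
  cents <- list(mk_ct(stats::rnorm(30), "DA1"),
                mk_ct(stats::rnorm(30), "DA2"), mk_ct(v3, "DA3"))
  r <- predict_da(stats::setNames(v3, genes), cents)
  expect_equal(r$da_call, "S3")
  expect_equal(unname(r$da_rhos["S3"]), 1)

  # identical first two centroids tie exactly: lower severity wins
  cents2 <- list(mk_ct(v3, "DA1"), mk_ct(v3, "DA2"),
                 mk_ct(stats::rnorm(30), "DA3"))
  r2 <- predict_da(stats::setNames(v3, genes), cents2)
  expect_equal(r2$da_call, "S1")
  expect_error(predict_da(stats::setNames(v3, genes), cents2[1:2]),
               "three")
})

test_that("classify_study produces one deterministic row per sample", {
  coll <- simulate_collection(synthetic_config(
    n_studies = 2L, n_genes = 500L, n_signature_genes = 30L,
    samples_per_group = 8L, seed = 95))
  tru <- coll$truth$signature
  ms <- ms_from_genes(tru$gene, tru$direction)
  ct <- build_centroid(coll$studies[1], ms)
  out1 <- classify_study(coll$studies[[2]], ms, ct)
  out2 <- classify_study(coll$studies[[2]], ms, ct)
  expect_identical(out1, out2)
  expect_equal(nrow(out1), ncol(coll$studies[[2]]$matrix))
  expect_true(all(out1$call %in% c("SLE", "HEALTHY")))
  expect_true(all((out1$rho >= 0.3) == (out1$call == "SLE")))
})
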