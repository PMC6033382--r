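test_that("self-similarity is perfectly concordant with binomial-tail confidence", {
  set.seed(51)
  genes <- sprintf("GN%03d", 1:10)
  sig <- make_sig("self", genes, sample(c(1L, -1L), 10, replace = TRUE),
                  stats::rexp(10), universe = 2000L)
  r <- signature_similarity(sig, sig)
  expect_equal(r$n_overlap, 10L)
  expect_equal(r$n_discordant, 0L)
  expect_equal(r$p_concordance, 2^-10)
  expect_equal(r$weighted_score,
               sum(sig$entries$confidence / max(sig$entries$confidence)))
  expect_true(r$significant)

  # the binomial tail crosses alpha = 0.01 between 6 and 7 shared genes
  s7 <- make_sig("a7", genes[1:7], rep(1L, 7), rep(1, 7), universe = 2000L)
  s6 <- make_sig("a6", genes[1:6], rep(1L, 6), rep(1, 6), universe = 2000L)
  expect_true(signature_similarity(s7, s7)$significant)
  expect_false(signature_similarity(s6, s6)$significant)
})

test_that("disjoint signatures are never similar", {
  a <- make_sig("a", c("G1", "G2"), c(1L, 1L), c(1, 1))
  b <- make_sig("b", c("G3", "G4"), c(1L, 1L), c(1, 1))
  r <- signature_similarity(a, b)
  expect_equal(r$n_overlap, 0L)
  expect_equal(r$weighted_score, 0)
  expect_false(r$significant)
})

test_that("concordance and overlap tails match direct-summation oracles", {
  # 10 shared genes, 9 concordant, uniform weights
  genes <- sprintf("GN%03d", 1:10)
  dirs_a <- rep(1L, 10)
  dirs_b <- c(rep(1L, 9), -1L)
  a <- make_sig("a", genes, dirs_a, rep(2, 10), universe = 500L)
  b <- make_sig("b", genes, dirs_b, rep(2, 10), universe = 500L)
  r <- signature_similarity(a, b)
  expect_equal(r$n_concordant, 9L)
  expect_equal(r$p_concordance, oracle_binom_tail(9, 10))
  expect_equal(oracle_binom_tail(9, 10), 11 / 1024)
  expect_equal(r$weighted_score, 9 - 1)  # uniform weights of 1
  expect_equal(r$p_overlap, oracle_hyper_tail(10, 10, 500, 10),
               tolerance = 1e-12)

  set.seed(52)
  pool <- sprintf("P%04d", 1:300)
  for (i in 1:20) {
    ga <- sample(pool, 30); gb <- sample(pool, 40)
    a <- make_sig("ra", ga, sample(c(1L, -1L), 30, TRUE), stats::rexp(30),
                  universe = 300L)
    b <- make_sig("rb", gb, sample(c(1L, -1L), 40, TRUE), stats::rexp(40),
                  universe = 280L)
    r <- signature_similarity(a, b)
    expect_equal(r$n_concordant + r$n_discordant, r$n_overlap)
    expect_equal(r$p_concordance,
                 oracle_binom_tail(r$n_concordant, r$n_overlap),
                 tolerance = 1e-12)
    expect_equal(r$p_overlap,
                 oracle_hyper_tail(r$n_overlap, 30, 280, 40),
                 tolerance = 1e-12)
    expect_lte(abs(r$weighted_score), r$n_overlap)
  }
})

test_that("similarity is symmetric and all_vs_all covers every pair", {
  set.seed(53)
  pool <- sprintf("P%04d", 1:200)
  sigs <- lapply(1:13, function(i) {
    k <- sample(20:60, 1)
    make_sig(paste0("sig", sprintf("%02d", i)), sample(pool, k),
             sample(c(1L, -1L), k, TRUE), stats::rexp(k), universe = 200L)
  })
  res <- all_vs_all(sigs)
  expect_equal(nrow(res), choose(13, 2))
  a <- signature_similarity(sigs[[2]], sigs[[9]])
  b <- signature_similarity(sigs[[9]], sigs[[2]])
  for (f in c("n_overlap", "n_concordant", "n_discordant",
              "weighted_score", "p_concordance", "p_overlap",
              "significant")) {
    expect_equal(a[[f]], b[[f]])
  }
  # permuting the input yields the same result set
  res2 <- all_vs_all(rev(sigs))
  key <- function(d) {
    k <- ifelse(d$sig_a < d$sig_b, paste(d$sig_a, d$sig_b),
                paste(d$sig_b, d$sig_a))
    d <- d[order(k), ]; rownames(d) <- NULL
    d[, c("n_overlap", "n_concordant", "weighted_score",
          "p_concordance", "p_overlap", "significant")]
  }
  expect_equal(key(res), key(res2))
})

test_that("the all-versus-all search scales to 167 signatures in under a minute", {
  set.seed(54)
  pool <- sprintf("P%05d", 1:10000)
  sigs <- lapply(1:167, function(i) {
    k <- sample(300:500, 1)
    make_sig(sprintf("sig%03d", i), sample(pool, k),
             sample(c(1L, -1L), k, TRUE), stats::rexp(k), universe = 10000L)
  })
  elapsed <- system.time(res <- all_vs_all(sigs))[["elapsed"]]
  expect_equal(nrow(res), choose(167, 2))
  expect_lt(elapsed, 60)
})

test_that("clusters are the connected components of the significance graph", {
  mk <- function(a, b, sig) data.frame(
    sig_a = a, sig_b = b, n_overlap = 10L, n_concordant = 10L,
    n_discordant = 0L, weighted_score = 10, p_concordance = 0.001,
    p_overlap = 0.001, significant = sig, stringsAsFactors = FALSE)
  res <- rbind(mk("A", "B", TRUE), mk("B", "C", TRUE), mk("D", "E", TRUE),
               mk("A", "D", FALSE), mk("C", "F", FALSE))
  cl <- cluster_signatures(res)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$members, c("A", "B", "C"))
  expect_equal(cl[[2]]$members, c("D", "E"))

  expect_length(cluster_signatures(mk("A", "B", FALSE)), 0L)
})

test_that("component clustering agrees with a naive closure oracle", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(4:20, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    ne <- sample(1:(2 * n), 1)
    ea <- sample(nodes, ne, replace = TRUE)
    eb <- sample(nodes, ne, replace = TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    if (length(ea) == 0) next
    res <- data.frame(sig_a = ea, sig_b = eb, n_overlap = 1L,
                      n_concordant = 1L, n_discordant = 0L,
                      weighted_score = 1, p_concordance = 0.001,
                      p_overlap = 0.001, significant = TRUE,
                      stringsAsFactors = FALSE)
    got <- lapply(cluster_signatures(res), `[[`, "members")
    touched <- sort(unique(c(ea, eb)))
    want <- oracle_components(touched, ea, eb)
    want <- want[vapply(want, length, 1L) >= 2]
    want <- want[order(-vapply(want, length, 1L),
                       vapply(want, `[[`, "", 1L))]
    expect_equal(got, unname(want))
  }
})

test_that("direction-shuffled null pairs rarely reach significance", {
  set.seed(56)
  genes <- sprintf("GN%03d", 1:30)
  alpha <- 0.01
  n_sig <- 0L
  for (i in 1:1000) {
    a <- make_sig("a", genes, sample(c(1L, -1L), 30, TRUE), rep(1, 30),
                  universe = 60L)
    b <- make_sig("b", genes, sample(c(1L, -1L), 30, TRUE), rep(1, 30),
                  universe = 60L)
    n_sig <- n_sig + signature_similarity(a, b, alpha)$significant
  }
  expect_lte(n_sig / 1000, 2 * alpha)
})
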