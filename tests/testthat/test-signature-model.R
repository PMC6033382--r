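test_that("signature round-trips losslessly through its TSV format", {
  sig <- make_sig("sigA", c("IFI16", "TLR9"), c(1L, -1L), c(3.2, 2.0),
                  universe = 5000L, study = "gse1",
                  contrast = c("healthy", "flare"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$signature_id, sig$signature_id)
  expect_identical(back$study_id, sig$study_id)
  expect_identical(back$contrast, sig$contrast)
  expect_identical(back$universe_size, sig$universe_size)
  expect_equal(back$entries, sig$entries)
})

test_that("random signatures round-trip exactly", {
  set.seed(11)
  pool <- sprintf("GN%04d", 1:500)
  for (i in 1:10) {
    k <- sample(1:80, 1)
    sig <- make_sig(paste0("s", i), sample(pool, k),
                    sample(c(1L, -1L), k, replace = TRUE),
                    round(stats::rexp(k, 1 / 3), 6), universe = 600L)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_signature(sig, path)
    expect_equal(read_signature(path)$entries, sig$entries)
  }
})

test_that("empty signatures are representable but flagged invalid", {
  sig <- gene_signature("empty", "st", c("a", "b"), NULL, 100L)
  expect_false(is_valid_signature(sig))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_false(is_valid_signature(back))
  expect_identical(back$universe_size, 100L)
})

test_that("malformed signature files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#signature_id=x", "#study_id=y", "#baseline=a", "#case=b",
               "#universe_size=10", "gene\tdirection\tconfidence",
               "TLR7\tup\t2.0", "TLR7\tdown\t1.0"), path)
  expect_error(read_signature(path), "TLR7")
  writeLines(c("#signature_id=x", "#study_id=y", "#baseline=a", "#case=b",
               "#universe_size=10", "gene\tdirection\tconfidence",
               "TLR7\tsideways\t2.0"), path)
  expect_error(read_signature(path), "direction")
})

test_that("expression studies read from TSV and validate samples", {
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  ph_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "IFI16\t1\t2\t3\t4",
               "TLR7\t5\t6\t7\t8",
               "MX1\t9\t10\t11\t12"), mat_path)
  writeLines(c("sample_id\tgroup\tstatus\tsledai",
               "s1\thealthy\tHEALTHY\t",
               "s2\thealthy\tHEALTHY\t",
               "s3\tsle\tSLE\t4",
               "s4\tsle\tSLE\t9"), ph_path)
  st <- read_expression_study(mat_path, ph_path, "demo")
  expect_s3_class(st, "expression_study")
  expect_equal(dim(st$matrix), c(3L, 4L))
  expect_identical(sort(rownames(st$matrix)), c("IFI16", "MX1", "TLR7"))
  expect_identical(st$phenotype$sledai, c(NA_integer_, NA_integer_, 4L, 9L))
})

test_that("duplicate probes collapse to the per-sample mean, case-insensitively", {
  mat <- rbind(Tlr7 = c(1, 2, 3, 4), TLR7 = c(3, 4, 5, 6),
               MX1 = c(0, 0, 1, 1))
  colnames(mat) <- paste0("s", 1:4)
  st <- make_study(mat, groups = c("healthy", "healthy", "sle", "sle"))
  expect_equal(nrow(st$matrix), 2L)
  expect_equal(unname(st$matrix["TLR7", ]), c(2, 3, 4, 5))

  # collapse is row-order invariant
  st2 <- make_study(mat[c(3, 2, 1), ], groups = c("healthy", "healthy",
                                                  "sle", "sle"))
  expect_equal(st$matrix, st2$matrix[rownames(st$matrix), ])
})

test_that("sample mismatches intersect with a warning; zero overlap errors", {
  mat <- matrix(1:8, 2, dimnames = list(c("A1", "B1"), paste0("s", 1:4)))
  ph5 <- data.frame(sample_id = paste0("s", 1:5),
                    group = "g", status = "SLE", sledai = NA)
  expect_warning(st <- expression_study(mat, ph5, "x"), "absent from matrix")
  expect_equal(ncol(st$matrix), 4L)
  expect_equal(nrow(st$phenotype), 4L)

  ph_none <- data.frame(sample_id = "zzz", group = "g", status = "SLE",
                        sledai = NA)
  expect_error(expression_study(mat, ph_none, "x"), "no samples shared")
})

test_that("non-numeric matrix cells are rejected naming the offending cell", {
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  ph_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "IFI16\t1\toops", "MX1\t2\t3"), mat_path)
  writeLines(c("sample_id\tgroup\tstatus\tsledai",
               "s1\tg\tSLE\t", "s2\tg\tSLE\t"), ph_path)
  expect_error(read_expression_study(mat_path, ph_path), "IFI16.*s2")
})

test_that("homolog mapping translates, resolves conflicts, drops discordance", {
  hm <- homolog_map(c("Tlr7", "Tlr7b", "Ifi202", "Ifi203"),
                    c("TLR7", "TLR7", "IFI16", "IFI16"))
  # direct mapping
  s1 <- make_sig("m1", "Tlr7", 1L, 4.0, universe = 50L)
  out1 <- map_homologs(s1, hm)
  expect_equal(out1$entries$gene, "TLR7")
  expect_equal(out1$entries$confidence, 4.0)

  # same target, concordant: max confidence wins
  s2 <- make_sig("m2", c("Tlr7", "Tlr7b"), c(1L, 1L), c(2.0, 5.0),
                 universe = 50L)
  out2 <- map_homologs(s2, hm)
  expect_equal(out2$entries$confidence, 5.0)

  # same target, discordant at equal confidence: gene dropped
  s3 <- make_sig("m3", c("Ifi202", "Ifi203"), c(1L, -1L), c(3.0, 3.0),
                 universe = 50L)
  out3 <- map_homologs(s3, hm)
  expect_false("IFI16" %in% out3$entries$gene)
  expect_equal(attr(out3, "n_discordant_dropped"), 1L)

  # unmapped genes dropped and counted
  s4 <- make_sig("m4", c("Tlr7", "NOVEL1"), c(1L, 1L), c(1.0, 1.0),
                 universe = 50L)
  out4 <- map_homologs(s4, hm)
  expect_equal(attr(out4, "n_unmapped"), 1L)
  expect_equal(nrow(out4$entries), 1L)
})

test_that("homolog mapping with an identity map is idempotent", {
  set.seed(3)
  genes <- sprintf("GN%03d", 1:40)
  hm <- homolog_map(genes, genes)
  sig <- make_sig("id", sample(genes, 15),
                  sample(c(1L, -1L), 15, replace = TRUE), stats::rexp(15),
                  universe = 40L)
  once <- map_homologs(sig, hm)
  twice <- map_homologs(once, hm)
  expect_equal(once$entries, twice$entries)
  expect_equal(sort(once$entries$gene), sort(sig$entries$gene))
})

test_that("gene symbols reject whitespace and empties", {
  expect_error(canonical_gene("TLR 7"), "whitespace")
  expect_error(canonical_gene(""), "non-empty")
  expect_identical(canonical_gene("ifi16"), "IFI16")
})
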