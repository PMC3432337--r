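make_pwm_file <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "AC  M001",
    "ID  TF_ALPHA",
    "P0      A      C      G      T",
    "01      10      0      0      0",
    "02      0      10      0      0",
    "03      0      0      10      0",
    "04      10      0      0      0",
    "//",
    "AC  M002",
    "ID  TF_BETA",
    "P0      A      C      G      T",
    "01      0      0      0      10",
    "02      0      0      0      10",
    "03      8      0      2      0",
    "//"), path)
  path
}

test_that("background sequences are GC- and length-matched and reproducible", {
  seqs <- c(probe1 = paste(rep(c("G", "C", "A", "T", "G"), 20), collapse = ""))
  bg <- generate_background(seqs, n = 500, seed = 42)
  expect_length(bg, 500)
  expect_true(all(nchar(bg) == 100))
  gc <- vapply(strsplit(bg, ""), function(b) mean(b %in% c("G", "C")),
               numeric(1))
  expect_gt(mean(gc), 0.57)
  expect_lt(mean(gc), 0.63)
  expect_identical(bg, generate_background(seqs, n = 500, seed = 42))
  expect_length(generate_background(seqs, n = 0, seed = 1), 0)
  expect_error(generate_background(c(x = "ACGN"), 10, 1), "position 4")
})

test_that("TRANSFAC parsing and PWM scanning behave at the extremes", {
  mats <- read_transfac_matrices(make_pwm_file())
  expect_named(mats, c("M001", "M002"))
  expect_equal(dim(mats$M001), c(4, 4))

  # consensus sequence scores 1.0 for its own matrix
  hits <- scan_pwm(c(s1 = "ACGA"), mats["M001"], score_threshold = 1.0)
  expect_gte(hits$counts["s1", "M001"], 1)

  # threshold 0 counts every window on both strands
  L <- 10
  seqs <- c(s1 = paste(rep("A", L), collapse = ""))
  h0 <- scan_pwm(seqs, mats, score_threshold = 0)
  expect_equal(sum(h0$counts), 2 * (L - 4 + 1) + 2 * (L - 3 + 1))

  # strand symmetry: reverse-complementing inputs preserves counts
  set.seed(8)
  rseqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1))
  names(rseqs) <- paste0("r", 1:5)
  fwd <- scan_pwm(rseqs, mats, 0.8)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(rseqs)))
  rev <- scan_pwm(rc, mats, 0.8)
  expect_equal(unname(fwd$counts), unname(rev$counts))

  bad <- tempfile(fileext = ".txt")
  writeLines(c("AC  M009", "P0 A C G T", "01 1 2 x 3", "//"), bad)
  expect_error(read_transfac_matrices(bad), "M009")
})

test_that("fisher_enrichment equals hypergeometric enumeration", {
  expect_equal(fisher_enrichment(0, 10, 0, 100), 1)
  expect_equal(fisher_enrichment(8, 10, 2, 10), 2126 / 184756,
               tolerance = 1e-12)
  # depletion is never more significant than its flipped table
  p_dep <- fisher_enrichment(1, 10, 5, 10)
  p_enr <- fisher_enrichment(5, 10, 1, 10)
  expect_gte(p_dep, p_enr)
  set.seed(13)
  for (i in 1:30) {
    n_cat <- sample(1:40, 1); n_bg <- sample(1:40, 1)
    k_cat <- sample(0:n_cat, 1); k_bg <- sample(0:n_bg, 1)
    expect_equal(fisher_enrichment(k_cat, n_cat, k_bg, n_bg),
                 fisher_enum_oracle(k_cat, n_cat, k_bg, n_bg),
                 tolerance = 1e-12)
  }
})

test_that("bonferroni_threshold divides alpha across matrices and categories", {
  expect_equal(signif(bonferroni_threshold(0.05, 459, 3), 3), 3.63e-05)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 10, 2), 0.005)
})

test_that("enrich_categories flags only genuinely enriched matrices", {
  tf <- c("M1", "M2")
  mk_hits <- function(k, n, tf_ids = tf) {
    counts <- matrix(0L, n, length(tf_ids),
                     dimnames = list(paste0("s", 1:n), tf_ids))
    if (k > 0) counts[1:k, 1] <- 1L
    counts[, 2] <- 1L   # M2 hits everything everywhere
    structure(list(counts = counts, tf_ids = tf_ids,
                   sequence_ids = rownames(counts)), class = "hit_table")
  }
  cat_hits <- list(hypo = mk_hits(50, 50))
  bg_hits <- mk_hits(100, 10000)
  res <- enrich_categories(cat_hits, bg_hits, alpha = 0.05,
                           n_tf_override = 459)
  expect_equal(nrow(res), 2)    # categories x tfs
  m1 <- res[res$tf_id == "M1", ]
  expect_true(m1$significant)
  expect_lt(m1$p_value, bonferroni_threshold(0.05, 459, 1))
  m2 <- res[res$tf_id == "M2", ]
  expect_false(m2$significant)  # identical rates are never enriched
  expect_equal(m2$p_value, 1)

  bad <- mk_hits(5, 10, tf_ids = c("M1", "M3"))
  expect_error(enrich_categories(list(x = bad), bg_hits), "M3")
})
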