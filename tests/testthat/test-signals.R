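test_that("compute_signal applies the signal/SE definitions", {
  rec <- data.frame(probe_id = "p1", channel = "treated", replicate = 1L,
                    F = 1000, B = 100, SD_F = 50, SD_B = 10,
                    Pix_F = 25, Pix_B = 25)
  out <- compute_signal(rec)
  expect_equal(out$y, 900)
  expect_equal(out$sigma, sqrt(104))
  expect_equal(out$sigma_rel, sqrt(104) / 900)
  expect_equal(out$y_log, log(900))
  expect_true(out$valid)

  # equal foreground/background forces the degenerate branch
  rec$B <- 1000
  out0 <- compute_signal(rec)
  expect_equal(out0$y, 0)
  expect_false(out0$valid)
  expect_true(is.na(out0$sigma_rel) && is.na(out0$y_log))

  # zero pixel variance
  rec$B <- 100; rec$SD_F <- 0; rec$SD_B <- 0
  expect_equal(compute_signal(rec)$sigma, 0)

  # pixel count below 1 is a malformed record naming the probe
  rec$Pix_F <- 0
  expect_error(compute_signal(rec), "p1")
})

test_that("compute_signal is scale-equivariant and supports log base 2", {
  set.seed(42)
  for (i in 1:20) {
    rec <- data.frame(probe_id = "p", channel = "control", replicate = 1L,
                      F = runif(1, 200, 5000), B = runif(1, 0, 150),
                      SD_F = runif(1, 0, 80), SD_B = runif(1, 0, 20),
                      Pix_F = sample(9:64, 1), Pix_B = sample(9:64, 1))
    c_fac <- runif(1, 0.1, 10)
    scaled <- rec
    scaled[c("F", "B", "SD_F", "SD_B")] <-
      scaled[c("F", "B", "SD_F", "SD_B")] * c_fac
    a <- compute_signal(rec); b <- compute_signal(scaled)
    expect_equal(b$y, c_fac * a$y)
    expect_equal(b$sigma, c_fac * a$sigma)
    expect_equal(b$sigma_rel, a$sigma_rel)
  }
  rec <- data.frame(probe_id = "p", channel = "control", replicate = 1L,
                    F = 1124, B = 100, SD_F = 1, SD_B = 1,
                    Pix_F = 25, Pix_B = 25)
  expect_equal(compute_signal(rec, log_base = 2)$y_log, 10)
})

test_that("read_probe_table round-trips the canonical TSV dialect", {
  rec <- make_raw_records(n_probes = 3, reps = 1)
  path <- write_probe_fixture(rec)
  got <- read_probe_table(path)
  expect_equal(nrow(got), 6)
  expect_equal(got$probe_id[1:3], rec$probe_id[1:3])
  expect_equal(got$F, rec$F)
  expect_equal(got$Pix_F, rec$Pix_F)

  # write -> read is the identity on valid records
  path2 <- write_probe_fixture(got)
  expect_equal(read_probe_table(path2), got)
})

test_that("read_probe_table reports schema and parse errors with locations", {
  rec <- make_raw_records(n_probes = 2, reps = 1)
  path <- write_probe_fixture(rec)

  tab <- utils::read.delim(path)
  tab$Pix_F <- NULL
  p_missing <- tempfile(fileext = ".tsv")
  utils::write.table(tab, p_missing, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_probe_table(p_missing), "Pix_F")

  lines <- readLines(path)
  lines[2] <- sub("^([^\t]*\t[^\t]*\t[^\t]*\t)[^\t]*", "\\1oops", lines[2])
  p_bad <- tempfile(fileext = ".tsv")
  writeLines(lines, p_bad)
  expect_error(read_probe_table(p_bad), "non-numeric")

  p_empty <- tempfile(fileext = ".tsv")
  writeLines(lines[1], p_empty)
  expect_equal(nrow(read_probe_table(p_empty)), 0)
})

test_that("gpr_like dialect expands both wavelengths per row", {
  tab <- data.frame(check.names = FALSE,
    ID = c("pA", "pB"),
    `F635 Median` = c(900, 1200), `B635 Median` = c(100, 110),
    `F635 SD` = c(40, 50), `B635 SD` = c(9, 10),
    `F635 Pixels` = c(25, 25), `B635 Pixels` = c(30, 30),
    `F532 Median` = c(850, 700), `B532 Median` = c(95, 90),
    `F532 SD` = c(35, 30), `B532 SD` = c(8, 7),
    `F532 Pixels` = c(25, 25), `B532 Pixels` = c(30, 30))
  path <- tempfile(fileext = ".txt")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_probe_table(path, dialect = "gpr_like", replicate = 2)
  expect_equal(nrow(got), 4)
  expect_setequal(unique(got$channel), c("treated", "control"))
  expect_true(all(got$replicate == 2))
  expect_equal(got$F[got$channel == "treated"], c(900, 1200))
  swapped <- read_probe_table(path, dialect = "gpr_like",
                              swap_channels = TRUE)
  expect_equal(swapped$F[swapped$channel == "control"], c(900, 1200))
})

test_that("build_dataset assembles matrices and enforces structure", {
  rec <- make_raw_records(n_probes = 2, reps = 3)
  ds <- build_dataset(rec, scale = "linear")
  expect_s3_class(ds, "meth_dataset")
  expect_equal(length(ds$probe_ids), 2)
  expect_equal(dim(ds$treated), c(2, 3))
  expect_equal(dim(ds$se_control), c(2, 3))
  expect_equal(ds$n_excluded, 0L)

  # a zero-signal replicate excludes the probe on the log scale only
  rec0 <- rec
  rec0$F[1] <- rec0$B[1]
  ds_log <- build_dataset(rec0, scale = "log")
  expect_equal(ds_log$n_excluded, 1L)
  expect_equal(length(ds_log$probe_ids), 1)
  expect_equal(ds_log$treated, log(exp(ds_log$treated)))

  # single-channel probe is structural
  expect_error(build_dataset(rec[rec$channel == "treated", ], "linear"),
               "only one channel")

  # duplicate key
  expect_error(build_dataset(rbind(rec, rec[1, ]), "linear"), "duplicate")
})
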