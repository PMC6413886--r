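test_that("gene matrix TSV round-trips and rejects malformed input", {
  gm <- tiny_gene_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_matrix(gm, path)
  back <- read_gene_matrix(path, "mRNA")
  expect_equal(unclass(back), unclass(gm), tolerance = 1e-12)
  expect_identical(modality(back), "mRNA")

  # duplicate gene row
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(read_gene_matrix(path, "mRNA"), "duplicate gene")

  # missing cell comes back as flagged-missing NA
  writeLines(c(lines[1], sub("\t[^\t]*$", "\tNA", lines[2]), lines[-(1:2)]),
             path)
  m2 <- read_gene_matrix(path, "mRNA")
  expect_true(is.na(m2[1, ncol(m2)]))
  expect_equal(sum(is.na(m2)), 1L)

  # non-numeric cell names the offender
  writeLines(c(lines[1], sub("\t[^\t]*$", "\toops", lines[2]),
               lines[-(1:2)]), path)
  expect_error(read_gene_matrix(path, "mRNA"), "non-numeric cell")
})

test_that("genomic instability index counts strict |log-ratio| > 1", {
  expect_equal(compute_gii(c(0, 0.2, -0.5, 0.9)), 0)
  expect_equal(compute_gii(c(1.2, 0.5, -2.0, 0.8)), 0.5)
  expect_equal(compute_gii(c(-1.0)), 0)  # boundary is strict
  x <- rnorm(200)
  expect_equal(compute_gii(x), compute_gii(-x))  # sign invariance
  expect_error(compute_gii(numeric(0)), "empty")
  expect_error(compute_gii(c(NA_real_)), "empty")
})

test_that("activity calling maps per-type tertiles to -1/0/+1", {
  vals <- matrix(1:100, nrow = 1,
                 dimnames = list("g1", paste0("s", 1:100)))
  gm <- gene_matrix(vals, "mRNA")
  act <- call_activity(gm, rep("ctA", 100))
  expect_equal(unname(act["g1", "s10"]), -1L)
  expect_equal(unname(act["g1", "s50"]), 0L)
  expect_equal(unname(act["g1", "s95"]), 1L)
  q <- quantile(1:100, c(0.33, 0.67), type = 7)
  expect_equal(sum(act == -1L), sum(1:100 < q[1]))
  expect_equal(sum(act == 1L), sum(1:100 > q[2]))

  # constant gene stays all-normal
  cm <- gene_matrix(matrix(5, 1, 50, dimnames = list("g1", paste0("s", 1:50))),
                    "mRNA")
  expect_true(all(call_activity(cm, rep("ctA", 50)) == 0L))

  # per-type quantiles are recomputed independently: the same raw value
  # lands in different states under shifted distributions
  set.seed(7)
  base <- rnorm(120)
  vals2 <- matrix(c(base, base + 10), nrow = 1,
                  dimnames = list("g1", paste0("s", 1:240)))
  types <- rep(c("A", "B"), each = 120)
  act2 <- call_activity(gene_matrix(vals2, "mRNA"), types)
  probe <- max(base)  # high for type A; probe - 10 is high within B shifted
  expect_equal(unname(act2[1, which.max(base)]), 1L)
  expect_equal(unname(act2[1, 120 + which.max(base)]), 1L)
  expect_equal(unname(act2[1, 120 + which.min(base)]), -1L)

  # under-sized cancer type warns and is called all-normal
  expect_warning(
    act3 <- call_activity(tiny_gene_matrix(n_samples = 5), rep("tiny", 5)),
    "states set to 0")
  expect_true(all(act3 == 0L))
})

test_that("activity states keep tertile fractions bounded on continuous data", {
  set.seed(11)
  gm <- gene_matrix(matrix(rnorm(20 * 300), 20, 300,
                           dimnames = list(paste0("g", 1:20),
                                           paste0("s", 1:300))), "mRNA")
  ct <- rep(c("A", "B", "C"), each = 100)
  act <- call_activity(gm, ct)
  for (type in unique(ct)) {
    sub <- act[, ct == type]
    expect_lte(max(rowMeans(sub == -1L)), 0.34)
    expect_lte(max(rowMeans(sub == 1L)), 0.34)
  }
})

test_that("pair states partition samples for DU and DD", {
  v <- c(-1L, -1L, -1L, 0L, 1L, 0L)
  r <- c(1L, 0L, -1L, 1L, -1L, 0L)
  du <- pair_states(v, r, "DU")
  expect_equal(du, c("rescued", "non_rescued", "non_rescued",
                     "other", "other", "other"))
  dd <- pair_states(v, r, "DD")
  expect_equal(dd, c("non_rescued", "non_rescued", "rescued",
                     "other", "other", "other"))
  expect_error(pair_states(v, r[-1], "DU"), "equal length")
  set.seed(3)
  va <- sample(c(-1L, 0L, 1L), 500, TRUE)
  ra <- sample(c(-1L, 0L, 1L), 500, TRUE)
  st <- pair_states(va, ra, "DU")
  expect_equal(sum(table(st)), 500L)  # states partition the samples
})

test_that("inverse-normal transform gives Blom scores and is rank-invariant", {
  x <- c(1, 2, 3, 4, 5)
  expected <- qnorm((rank(x) - 3 / 8) / (5 + 1 / 4))
  got <- inverse_normal_transform(x)
  expect_equal(got, expected)
  expect_equal(got[3], 0)
  expect_equal(got, -rev(got))  # symmetric

  set.seed(5)
  y <- rexp(100)
  expect_equal(inverse_normal_transform(y), inverse_normal_transform(exp(y)))
  expect_true(all(diff(inverse_normal_transform(sort(y))) > 0))
  expect_error(inverse_normal_transform(rep(2, 10)), "all values equal")
  expect_error(inverse_normal_transform(3), "at least 2")

  z <- inverse_normal_transform(rnorm(1000))
  skew <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(skew), 0.1)
})

test_that("clinical table validation enforces invariants", {
  cl <- simulate_survival(50, 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(cl[, setdiff(names(cl), "ind")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  back <- read_clinical(path)
  expect_equal(nrow(back), 50)
  bad <- cl
  bad$event[1] <- 2L
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical(path), "event")
})
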