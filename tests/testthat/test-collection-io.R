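test_that("connectome_collection validates dimensions, labels and weights", {
  set.seed(101)
  mats <- replicate(4, rspd(3), simplify = FALSE)
  coll <- connectome_collection(mats, labels = c("a", "a", "b", "b"))
  expect_s3_class(coll, "connectome_collection")
  expect_equal(length(coll), 4)
  expect_equal(coll$P, 3)
  # idempotent coercion
  expect_identical(connectome_collection(coll), coll)
  # dimension mismatch names the offending matrix
  bad <- mats
  bad[[3]] <- rspd(4)
  expect_error(connectome_collection(bad), "matrix 3")
  # non-SPD member names its index
  bad2 <- mats
  bad2[[2]] <- diag(c(1, -1, 1))
  expect_error(connectome_collection(bad2), "matrix 2")
  expect_error(connectome_collection(mats, labels = c("a", "b")), "length N")
  expect_error(connectome_collection(mats, weights = c(1, 1, -1, 1)),
               "strictly positive")
  # subsetting keeps labels aligned
  sub <- coll[3:4]
  expect_equal(sub$labels, c("b", "b"))
  expect_equal(sub$matrices[[1]], mats[[3]], tolerance = 1e-15)
})

test_that("split_by_group partitions a labelled collection", {
  set.seed(102)
  mats <- replicate(5, rspd(2), simplify = FALSE)
  coll <- connectome_collection(mats, labels = c("x", "y", "x", "y", "y"))
  gs <- split_by_group(coll)
  expect_named(gs, c("x", "y"))
  expect_equal(length(gs$x), 2)
  expect_equal(length(gs$y), 3)
  expect_equal(gs$y$matrices[[3]], mats[[5]], tolerance = 1e-15)
  expect_error(split_by_group(connectome_collection(mats)), "no labels")
})

test_that("matrix file round-trip preserves full precision", {
  set.seed(103)
  G <- rspd(4)
  p <- tempfile(fileext = ".txt")
  write_matrix_file(G, p)
  back <- read_matrix_file(p)
  expect_identical(back, unclass(G))
  # comma-delimited input is accepted too
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("# P 2", "2,0.5", "0.5, 2"), p2)
  expect_equal(read_matrix_file(p2), matrix(c(2, 0.5, 0.5, 2), 2, 2))
  # malformed inputs name the file and the check
  p3 <- tempfile()
  writeLines(c("1 2 3", "4 5"), p3)
  expect_error(read_matrix_file(p3), "ragged")
  p4 <- tempfile()
  writeLines(c("1 2 3", "4 5 6"), p4)
  expect_error(read_matrix_file(p4), "square")
  p5 <- tempfile()
  writeLines(c("1 0", "0 -1"), p5)
  expect_error(read_matrix_file(p5), "positive definite")
  expect_equal(read_matrix_file(p5, validate = FALSE), diag(c(1, -1)))
})

test_that("collection container round-trips with stable lexicographic order", {
  set.seed(104)
  mats <- replicate(3, rspd(3), simplify = FALSE)
  p <- tempfile(fileext = ".txt")
  write_matrix_collection(mats, p, ids = c("zeta", "alpha", "mid"))
  back <- read_matrix_collection(p)
  expect_equal(attr(back, "ids"), c("alpha", "mid", "zeta"))
  expect_identical(back$matrices[[1]], mats[[2]])  # 'alpha' was input #2
  expect_identical(back$matrices[[3]], mats[[1]])
  # labels sidecar joins by id; missing label errors with the id named
  lp <- tempfile(fileext = ".tsv")
  write_labels_table(c("alpha", "mid", "zeta"), c("g1", "g2", "g1"), lp)
  lab <- read_matrix_collection(p, labels = lp)
  expect_equal(lab$labels, c("g1", "g2", "g1"))
  lp2 <- tempfile(fileext = ".tsv")
  write_labels_table(c("alpha", "mid"), c("g1", "g2"), lp2)
  expect_error(read_matrix_collection(p, labels = lp2), "zeta")
})

test_that("a directory of per-subject files reads as a collection", {
  set.seed(105)
  d <- tempfile()
  dir.create(d)
  m1 <- rspd(2); m2 <- rspd(2)
  write_matrix_file(m1, file.path(d, "sub-b.txt"))
  write_matrix_file(m2, file.path(d, "sub-a.txt"))
  coll <- read_matrix_collection(d)
  expect_equal(attr(coll, "ids"), c("sub-a", "sub-b"))
  expect_identical(coll$matrices[[1]], unclass(m2))
  d2 <- tempfile()
  dir.create(d2)
  expect_error(read_matrix_collection(d2), "no files")
})

test_that("results tables round-trip at full precision", {
  df <- data.frame(method = c("a", "b"), value = c(pi, exp(1) * 1e-12),
                   n = c(3L, 4L), stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_results_table(df, p)
  back <- read_results_table(p)
  expect_identical(back$method, df$method)
  expect_identical(back$value, df$value)
  expect_identical(back$n, df$n)
})

test_that("run manifest records command, config, seeds and version", {
  p <- tempfile(fileext = ".json")
  write_run_manifest("mean", list(estimator = "gd", step_size = 0.5),
                     seeds = c(1L, 42L), path = p)
  m <- jsonlite::read_json(p)
  expect_equal(m$command, "mean")
  expect_equal(m$config$estimator, "gd")
  expect_equal(unlist(m$seeds), c(1L, 42L))
  expect_true(nzchar(m$artifact_version))
  expect_true(nzchar(m$timestamp))
})
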