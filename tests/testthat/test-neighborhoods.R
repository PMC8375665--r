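test_that("a cell at a window center is counted; closed-ball at exactly r", {
  df <- data.frame(sample_id = "a", x = c(0, 50), y = c(0, 0), CD8 = 0)
  tab <- cell_table(df)
  tab$cells$phenotype <- "A"
  nt <- raster_neighborhoods(tab, r = 50, s = 50)
  first <- nt$nb[nt$nb$x == 0 & nt$nb$y == 0, ]
  # the cell at the center plus the cell at distance exactly 50 (closed ball)
  expect_equal(first$A, 2)
})

test_that("raster counts match the exhaustive all-pairs oracle", {
  set.seed(99)
  n <- 1000
  df <- data.frame(sample_id = "a", x = runif(n, 0, 600),
                   y = runif(n, 0, 400), CD8 = 0)
  tab <- cell_table(df)
  tab$cells$phenotype <- sample(c("A", "B", "C"), n, replace = TRUE)
  nt <- raster_neighborhoods(tab, r = 50, s = 50, drop_empty = FALSE)
  oracle <- brute_counts(as.matrix(nt$nb[, c("x", "y")]), tab$cells, 50)
  for (ph in c("A", "B", "C")) {
    expect_identical(as.integer(nt$nb[[ph]]), as.integer(oracle[, ph]))
  }
})

test_that("counts are translation equivariant", {
  set.seed(4)
  df <- data.frame(sample_id = "a", x = runif(200, 0, 300),
                   y = runif(200, 0, 300), CD8 = 0)
  tab <- cell_table(df); tab$cells$phenotype <- "A"
  nt1 <- raster_neighborhoods(tab, r = 50, s = 50)
  tab$cells$x <- tab$cells$x + 123.4
  tab$cells$y <- tab$cells$y - 56.7
  nt2 <- raster_neighborhoods(tab, r = 50, s = 50)
  expect_equal(nt1$nb$A, nt2$nb$A)
  expect_equal(nt2$nb$x - nt1$nb$x, rep(123.4, nrow(nt1$nb)))
})

test_that("with s >= 2r no cell is counted twice", {
  set.seed(5)
  df <- data.frame(sample_id = "a", x = runif(500, 0, 1000),
                   y = runif(500, 0, 1000), CD8 = 0)
  tab <- cell_table(df); tab$cells$phenotype <- "A"
  nt <- raster_neighborhoods(tab, r = 50, s = 100, drop_empty = FALSE)
  centers <- as.matrix(nt$nb[, c("x", "y")])
  hits <- vapply(seq_len(nrow(tab$cells)), function(j) {
    sum(sqrt((centers[, 1] - tab$cells$x[j])^2 +
             (centers[, 2] - tab$cells$y[j])^2) <= 50)
  }, numeric(1))
  expect_true(all(hits <= 1))
  expect_equal(sum(nt$nb$A), sum(hits))
})

test_that("segment landmarks are counted by point-to-segment distance", {
  df <- data.frame(sample_id = "a", x = c(0, 200), y = c(0, 0), CD8 = 0)
  tab <- cell_table(df); tab$cells$phenotype <- "A"
  vessel <- landmark_set("vessel_segment",
                         segments = rbind(c(0, 40, 200, 40)),
                         sample_id = "a")
  nt <- raster_neighborhoods(tab, landmarks = vessel, r = 50, s = 50,
                             drop_empty = FALSE)
  # centers above the spanned x range sit 40 um from the line; corner
  # centers beyond the segment ends are farther than r and excluded
  spanned <- nt$nb$x <= 200 & abs(nt$nb$y - 40) <= 50
  expect_true(all(nt$nb$vessel[spanned] == 1))
  expect_true(all(nt$nb$vessel[nt$nb$x > 210] == 0))
})

test_that("normalization modes are correct and invertible", {
  counts <- cbind(A = c(10L, 0L, 3L), B = c(0L, 5L, 1L))
  nt <- toy_nbhd(counts)
  dens <- normalize_neighborhoods(nt, "density")
  expect_equal(dens$nb$A[1], 10 / (pi * 50^2))
  comp <- normalize_neighborhoods(nt, "composition")
  expect_equal(comp$nb$A[1], 1)             # single-phenotype window
  expect_equal(comp$nb$A + comp$nb$B, c(1, 1, 1))
  expect_equal(as.matrix(denormalize_neighborhoods(dens)$nb[, c("A", "B")]),
               as.matrix(nt$nb[, c("A", "B")]), ignore_attr = TRUE)
  expect_equal(as.matrix(denormalize_neighborhoods(comp)$nb[, c("A", "B")]),
               as.matrix(nt$nb[, c("A", "B")]), ignore_attr = TRUE)
  expect_error(normalize_neighborhoods(dens, "composition"), "counts")
})

test_that("empty tables warn and unlabeled tables error", {
  empty <- cell_table(data.frame(sample_id = character(), x = numeric(),
                                 y = numeric(), CD8 = numeric()))
  expect_warning(raster_neighborhoods(empty), "no cells")
  unlabeled <- cell_table(data.frame(sample_id = "a", x = 1, y = 1,
                                     CD8 = 0))
  expect_error(raster_neighborhoods(unlabeled), "labeled")
})
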