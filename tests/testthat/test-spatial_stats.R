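test_that("perfectly linear counts give r = +1 / -1", {
  nt <- toy_nbhd(cbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(3, 2, 1)))
  cm <- correlation_matrix(nt)
  expect_equal(cm$r["A", "B"], 1)
  expect_equal(cm$r["A", "C"], -1)
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$p["A", "B"], 0)
})

test_that("p-values match an independent t-transform evaluation", {
  # closed form at r = 0.5, n = 12
  t_exp <- 0.5 * sqrt((12 - 2) / (1 - 0.25))
  expect_equal(t_exp, 1.8257418, tolerance = 1e-6)
  p_exp <- 2 * (1 - stats::pt(t_exp, df = 10))
  expect_lt(abs(cor_pvalue(0.5, 12) - p_exp), 1e-10)

  # cross-check against stats::cor.test on random data
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    ct <- stats::cor.test(x, y)
    expect_lt(abs(cor_pvalue(stats::cor(x, y), 20) - ct$p.value), 1e-10)
  }
})

test_that("degenerate correlation inputs are handled", {
  nt <- toy_nbhd(cbind(A = c(1, 2, 3), B = c(5, 5, 5)))
  cm <- correlation_matrix(nt)
  expect_true(is.na(cm$r["A", "B"]))     # zero variance -> missing
  tiny <- toy_nbhd(cbind(A = c(1, 2), B = c(2, 1)))
  expect_error(correlation_matrix(tiny), "insufficient")
  one <- toy_nbhd(cbind(A = c(1, 2, 3)))
  expect_error(correlation_matrix(one), "labels")
})

test_that("correlation matrix is invariant to label order", {
  set.seed(8)
  counts <- cbind(A = rpois(30, 3), B = rpois(30, 5), C = rpois(30, 2))
  cm1 <- correlation_matrix(toy_nbhd(counts))
  cm2 <- correlation_matrix(toy_nbhd(counts[, c("C", "A", "B")]))
  expect_equal(cm1$r["A", "B"], cm2$r["A", "B"])
  expect_equal(cm1$p["B", "C"], cm2$p["B", "C"])
})

test_that("the fitted border tracks an analytic disk", {
  fx <- disk_border_fixture(radius = 300, s = 50, seed = 13)
  border <- fit_border(fx$nt, theta = fx$theta, sample_id = "d1")
  verts <- rbind(border$segments[, 1:2], border$segments[, 3:4])
  vr <- sqrt(verts[, 1]^2 + verts[, 2]^2)
  expect_true(all(abs(vr - 300) <= 50))   # within one grid step
})

test_that("theta = 0 keeps all spot windows; smaller blobs are discarded", {
  set.seed(6)
  spots <- landmark_set("cea_spot",
                        points = rbind(cbind(runif(40, 0, 100),
                                             runif(40, 0, 100)),
                                       c(900, 900)),
                        sample_id = "a")
  df <- data.frame(sample_id = "a", x = c(0, 1000), y = c(0, 1000),
                   CD8 = 0)
  tab <- cell_table(df); tab$cells$phenotype <- "other"
  nt <- raster_neighborhoods(tab, landmarks = spots, r = 50, s = 50)
  expect_message(border <- fit_border(nt, theta = 0, sample_id = "a"),
                 "largest")
  # the isolated far spot's window was dropped with its component
  idx <- which(border$mask, arr.ind = TRUE)
  expect_true(all(border$gx[idx[, 1]] < 500))
  expect_true(sum(border$mask) >= 1)
  expect_error(fit_border(nt, theta = 1e6, sample_id = "a"), "theta")
})

test_that("signed distances carry the inside-positive convention", {
  fx <- disk_border_fixture(radius = 300, s = 50, seed = 17)
  border <- fit_border(fx$nt, theta = fx$theta, sample_id = "d1")
  probes <- rbind(c(0, 0), c(150, 0), c(0, -150), c(350, 0), c(0, 360),
                  c(-355, 10))
  d <- signed_distance_to_border(probes, border)$distance
  expect_true(all(abs(d - c(300, 150, 150, -50, -60, -55)) <= 50))
  expect_true(all(d[1:3] > 0))            # inside: positive
  expect_true(all(d[4:6] < 0))            # outside: negative
})

test_that("border distances match a brute-force oracle", {
  fx <- disk_border_fixture(radius = 300, s = 50, seed = 19)
  border <- fit_border(fx$nt, theta = fx$theta, sample_id = "d1")
  set.seed(1)
  probes <- cbind(runif(50, -400, 400), runif(50, -400, 400))
  d <- abs(signed_distance_to_border(probes, border)$distance)
  oracle <- vapply(seq_len(nrow(probes)), function(i) {
    brute_min_segment_distance(probes[i, 1], probes[i, 2], border$segments)
  }, numeric(1))
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("nearest distances to segments and points are exact", {
  vessel <- landmark_set("vessel_segment",
                         segments = rbind(c(0, 0, 0, 100)),
                         sample_id = "a")
  d <- nearest_distance(rbind(c(30, 50), c(0, 50), c(10, 110)), vessel)
  expect_equal(d$distance, c(30, 0, sqrt(100 + 100)))
  spots <- landmark_set("cea_spot", points = rbind(c(5, 5), c(50, 50)))
  d2 <- nearest_distance(rbind(c(5, 5), c(40, 50)), spots)
  expect_equal(d2$distance, c(0, 10))
})

test_that("distance summaries report the proximal fraction", {
  prof <- tibble::tibble(x = 0, y = 0,
                         distance = c(5, 10, 30, 40),
                         phenotype = c("A", "A", "A", "B"))
  class(prof) <- c("distance_profile", class(prof))
  s <- summarize_distances(prof, proximal_um = 25)
  expect_equal(s$frac_proximal[s$phenotype == "A"], 2 / 3)
  expect_equal(s$n, c(3, 1))
})

test_that("planted colocalization and segregation give the right signs", {
  signs <- vapply(1:10, function(sd) {
    tis <- truth_labeled_tissue(tissue_spec(seed = sd))
    nt <- raster_neighborhoods(tis$table, landmarks = tis$landmarks,
                               r = 50, s = 50)
    cm <- correlation_matrix(nt)
    c(coloc = cm$r["DC2", "MHCII+_Mf"],
      seg = cm$r["CD206_Mf", "MHCII-_Mf"])
  }, numeric(2))
  expect_true(all(signs["coloc", ] > 0))
  expect_true(all(signs["seg", ] < 0))
})

test_that("channel intensity bands enter the correlation space", {
  tis <- truth_labeled_tissue(tissue_spec(seed = 23))
  nt <- raster_neighborhoods(tis$table, landmarks = tis$landmarks,
                             r = 50, s = 50)
  nt <- add_channel_bands(nt, tis$table, "PDL1")
  expect_true(all(c("PDL1_int", "PDL1_hi") %in% names(nt$nb)))
  cm <- correlation_matrix(nt)
  # activated myeloid cells carry intermediate PD-L1, so the intermediate
  # band colocalizes with the perivascular DC population
  expect_gt(cm$r["DC2", "PDL1_int"], 0)
})
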