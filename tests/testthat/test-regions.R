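test_that("noise-free archetypes are recovered exactly (ARI = 1)", {
  arch <- generate_archetypes(n = 120, k = 2, noise_sd = 0, seed = 2)
  model <- train_regions(arch$nt, k = 2, seed = 2)
  nt <- assign_regions(arch$nt, model)
  ari <- mclust::adjustedRandIndex(nt$nb$region, arch$truth)
  expect_equal(ari, 1)
})

test_that("identical neighborhoods collapse to one region; k too large errors", {
  counts <- matrix(3, 40, 4,
                   dimnames = list(NULL, c("A", "B", "C", "D")))
  nt <- toy_nbhd(counts)
  model <- train_regions(nt, k = 1, seed = 1)
  nt <- assign_regions(nt, model)
  expect_equal(unique(nt$nb$region), "R1")
  expect_error(train_regions(nt, k = 5, seed = 1), "occupied")
})

test_that("training is deterministic given the seed", {
  arch <- generate_archetypes(n = 200, k = 3, seed = 5)
  m1 <- train_regions(arch$nt, k = 3, seed = 7)
  m2 <- train_regions(arch$nt, k = 3, seed = 7)
  expect_identical(m1$som$codebook, m2$som$codebook)
  expect_identical(assign_regions(arch$nt, m1)$nb$region,
                   assign_regions(arch$nt, m2)$nb$region)
})

test_that("re-assigning the training data reproduces training regions", {
  arch <- generate_archetypes(n = 200, k = 3, seed = 6)
  model <- train_regions(arch$nt, k = 3, seed = 6)
  train_regions_lab <- paste0("R", model$node_region[model$som$bmu])
  expect_identical(assign_regions(arch$nt, model)$nb$region,
                   train_regions_lab)
})

test_that("held-out archetype neighborhoods classify correctly", {
  train <- generate_archetypes(n = 300, k = 3, noise_sd = 0, seed = 11)
  test <- generate_archetypes(n = 150, k = 3, noise_sd = 0, seed = 12)
  model <- train_regions(train$nt, k = 3, seed = 11)
  pred_train <- assign_regions(train$nt, model)$nb$region
  pred_test <- assign_regions(test$nt, model)$nb$region
  # map regions to archetypes via the training assignment
  regions <- sort(unique(pred_train))
  map <- stats::setNames(vapply(regions, function(rg) {
    as.integer(names(which.max(table(train$truth[pred_train == rg]))))
  }, integer(1)), regions)
  accuracy <- mean(map[pred_test] == test$truth)
  expect_gte(accuracy, 0.99)
})

test_that("region summary yields exact fold changes and prevalences", {
  counts <- cbind(A = c(4, 4, 0, 0), B = c(1, 1, 1, 1))
  nt <- toy_nbhd(counts, region = c("R1", "R1", "R2", "R2"))
  nt$nb$sample_id <- c("s1", "s1", "s1", "s2")
  s <- region_summary(nt, cd8_labels = "A", tumor_label = "B")
  expect_equal(unname(s$heatmap["R1", "A"]), 2)   # 4 vs overall mean 2
  expect_equal(unname(s$heatmap[, "B"]), c(1, 1))
  expect_equal(rowSums(s$prevalence), c(s1 = 1, s2 = 1))
  expect_equal(unname(s$prevalence["s1", ]), c(2 / 3, 1 / 3))
  # brute-force tabulation oracle
  tab <- table(nt$nb$sample_id, nt$nb$region)
  expect_equal(unname(s$prevalence),
               unname(as.matrix(tab / rowSums(tab))))
})

test_that("heatmap is invariant to duplicating every neighborhood", {
  arch <- generate_archetypes(n = 150, k = 3, seed = 9)
  model <- train_regions(arch$nt, k = 3, seed = 9)
  nt <- assign_regions(arch$nt, model)
  dup <- nt
  dup$nb <- rbind(nt$nb, nt$nb)
  s1 <- region_summary(nt, cd8_labels = "C01", tumor_label = "C04")
  s2 <- region_summary(dup, cd8_labels = "C01", tumor_label = "C04")
  expect_equal(s1$heatmap, s2$heatmap)
})

test_that("single-region prevalence is 1 for every sample", {
  counts <- matrix(2, 30, 3, dimnames = list(NULL, c("A", "B", "C")))
  nt <- toy_nbhd(counts)
  nt$nb$sample_id <- rep(c("s1", "s2", "s3"), each = 10)
  model <- train_regions(nt, k = 1, seed = 3)
  s <- region_summary(assign_regions(nt, model),
                      cd8_labels = "A", tumor_label = "B")
  expect_true(all(s$prevalence[, "R1"] == 1))
})

test_that("feature mismatch on assignment is caught", {
  arch <- generate_archetypes(n = 60, k = 2, seed = 4)
  model <- train_regions(arch$nt, k = 2, seed = 4)
  other <- toy_nbhd(cbind(A = 1:12, B = 12:1))
  expect_error(assign_regions(other, model), "feature mismatch")
})

test_that("the embedding separates archetypes and is reproducible", {
  arch <- generate_archetypes(n = 150, k = 2, seed = 15)
  emb1 <- embed_neighborhoods(arch$nt, seed = 15)
  emb2 <- embed_neighborhoods(arch$nt, seed = 15)
  expect_equal(emb1$umap1, emb2$umap1, tolerance = 1e-12)
  xy <- cbind(emb1$umap1, emb1$umap2)
  cents <- rbind(colMeans(xy[arch$truth == 1, ]),
                 colMeans(xy[arch$truth == 2, ]))
  between <- sqrt(sum((cents[1, ] - cents[2, ])^2))
  within <- max(vapply(1:2, function(k) {
    pts <- xy[arch$truth == k, ]
    cc <- colMeans(pts)
    max(sqrt((pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2))
  }, numeric(1)))
  expect_gt(between, within)
  expect_error(embed_neighborhoods(toy_nbhd(cbind(A = 1:5, B = 5:1))),
               "too few")
})

test_that("duplicate rows land on near-coincident embedding points", {
  arch <- generate_archetypes(n = 100, k = 2, seed = 18)
  nt <- arch$nt
  nt$nb <- rbind(nt$nb, nt$nb[1, ])        # duplicate the first row
  emb <- embed_neighborhoods(nt, seed = 18)
  d_dup <- sqrt((emb$umap1[101] - emb$umap1[1])^2 +
                (emb$umap2[101] - emb$umap2[1])^2)
  span <- max(dist(cbind(emb$umap1, emb$umap2)))
  expect_lt(d_dup, 0.05 * span)
})
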