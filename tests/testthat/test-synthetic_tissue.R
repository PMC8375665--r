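test_that("uniform placements stay inside the domain", {
  spec <- tissue_spec(domain = c(800, 600),
                      nest = list(center = c(400, 300), radius = 200),
                      vessels = list(n = 2, length_mean = 150,
                                     length_sd = 20),
                      populations = list(
                        other = list(n = 100, placement = "uniform_tissue")),
                      n_cea_spots = 10, seed = 5)
  tis <- generate_tissue(spec)
  cells <- tis$table$cells
  expect_equal(nrow(cells), 100)
  expect_true(all(cells$x >= 0 & cells$x <= 800))
  expect_true(all(cells$y >= 0 & cells$y <= 600))
})

test_that("generation is deterministic given the seed", {
  a <- generate_tissue(tissue_spec(seed = 9))
  b <- generate_tissue(tissue_spec(seed = 9))
  expect_identical(a$table$cells, b$table$cells)
  expect_identical(a$landmarks$vessel$segments, b$landmarks$vessel$segments)
  c <- generate_tissue(tissue_spec(seed = 10))
  expect_false(identical(a$table$cells$x, c$table$cells$x))
})

test_that("invalid specs are rejected", {
  expect_error(tissue_spec(nest = list(center = c(0, 0), radius = 300)),
               "inside the domain")
  expect_error(tissue_spec(capsule_width = 0, populations = list(
    a = list(n = 5, placement = "capsule_ring"))), "capsule_width")
  expect_error(tissue_spec(populations = list(
    a = list(n = 5, placement = "on_the_moon"))), "unknown placement")
})

test_that("perivascular distances follow the Rayleigh law", {
  spec <- tissue_spec(populations = list(
    DC2 = list(n = 2000, placement = "perivascular", sigma = 10)),
    seed = 21)
  tis <- generate_tissue(spec)
  d <- nearest_distance(tis$table, tis$landmarks$vessel)$distance
  p_expect <- prayleigh(25, 10)            # 1 - exp(-3.125)
  mc_sd <- sqrt(p_expect * (1 - p_expect) / 2000)
  expect_lt(abs(mean(d < 25) - p_expect), 3 * mc_sd)
  ks <- suppressWarnings(
    stats::ks.test(d, function(q) prayleigh(q, 10)))
  expect_gt(ks$p.value, 0.01)
})

test_that("capsule and nest placements respect their zones", {
  spec <- tissue_spec(populations = list(
    "CD206_Mf" = list(n = 300, placement = "capsule_ring"),
    "MHCII-_Mf" = list(n = 300, placement = "inside_nest")),
    seed = 2)
  tis <- generate_tissue(spec)
  cells <- tis$table$cells
  r <- sqrt((cells$x - 500)^2 + (cells$y - 500)^2)
  expect_true(all(r[cells$placement == "inside_nest"] <= 300))
  caps <- r[cells$placement == "capsule_ring"]
  expect_true(all(caps >= 300 & caps <= 400))
})

test_that("cohort metadata reproduces the linked fold change exactly", {
  cohort <- generate_cohort(cohort_spec(n_samples = 8, seed = 3))
  fc <- volume_fold_change(cohort$metadata)
  expect_equal(fc$fold_change, cohort$fold_change, tolerance = 1e-10)
  expect_true(all(cohort$fold_change > 0))
})

test_that("a noiseless link makes fold change strictly decreasing in phi", {
  cohort <- generate_cohort(cohort_spec(n_samples = 10, sigma_fc = 0,
                                        seed = 4))
  expect_true(all(diff(cohort$fold_change[order(cohort$phi)]) < 0))
})

test_that("b = 0 decouples fold change from infiltration", {
  rs <- vapply(1:10, function(sd) {
    cohort <- generate_cohort(cohort_spec(n_samples = 20, b = 0,
                                          seed = sd))
    stats::cor(cohort$phi, cohort$fold_change)
  }, numeric(1))
  # null correlations: small on average, both signs represented
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("planted archetypes have the advertised geometry", {
  arch <- generate_archetypes(n = 300, k = 3, separation = 6,
                              noise_sd = 1, seed = 8)
  expect_equal(nrow(arch$nt$nb), 300)
  expect_length(arch$truth, 300)
  x <- as.matrix(arch$nt$nb[, arch$nt$phenotypes])
  cents <- t(vapply(1:3, function(k) colMeans(x[arch$truth == k, ]),
                    numeric(ncol(x))))
  seps <- as.numeric(stats::dist(cents))
  expect_true(all(seps > 5 & seps < 7))   # planted separation 6
})
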