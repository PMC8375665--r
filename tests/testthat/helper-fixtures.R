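# shared in-code fixtures; nothing is read from disk

# minimal cell table: n cells of given phenotypes scattered in a box
toy_cells <- function(n = 10, phenotypes = "A", box = c(500, 500),
                      seed = 1) {
  set.seed(seed)
  df <- data.frame(sample_id = "t1",
                   x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
                   CD8 = runif(n, 0, 10), CD11c = runif(n, 0, 10))
  tab <- cell_table(df, channels = c("CD8", "CD11c"),
                    imaged_volume = prod(box) / 1e6)
  tab$cells$phenotype <- rep_len(phenotypes, n)
  tab
}

# neighborhood table built directly from a count matrix
toy_nbhd <- function(counts, landmark_cols = character(0),
                     sample_id = "t1", r = 50, s = 50, region = NULL) {
  counts <- as.matrix(counts)
  ph <- setdiff(colnames(counts), landmark_cols)
  nb <- tibble::tibble(sample_id = sample_id,
                       x = seq_len(nrow(counts)) * s, y = 0)
  nb <- cbind(nb, tibble::as_tibble(as.data.frame(counts)))
  if (!is.null(region)) nb$region <- region
  tmemap:::new_neighborhood_table(tibble::as_tibble(nb), r = r, s = s,
                                  phenotypes = ph,
                                  landmarks = landmark_cols)
}

# brute-force all-pairs neighborhood counting oracle (independent of the
# package's blocked implementation)
brute_counts <- function(centers, cells, r) {
  phenos <- sort(unique(cells$phenotype))
  out <- matrix(0L, nrow(centers), length(phenos),
                dimnames = list(NULL, phenos))
  for (i in seq_len(nrow(centers))) {
    for (j in seq_len(nrow(cells))) {
      d <- sqrt((centers[i, 1] - cells$x[j])^2 +
                (centers[i, 2] - cells$y[j])^2)
      if (d <= r) {
        out[i, cells$phenotype[j]] <- out[i, cells$phenotype[j]] + 1L
      }
    }
  }
  out
}

# brute-force point-to-segment minimum distance oracle
brute_min_segment_distance <- function(px, py, segs) {
  best <- Inf
  for (j in seq_len(nrow(segs))) {
    x1 <- segs[j, 1]; y1 <- segs[j, 2]; x2 <- segs[j, 3]; y2 <- segs[j, 4]
    vx <- x2 - x1; vy <- y2 - y1
    t <- ((px - x1) * vx + (py - y1) * vy) / (vx^2 + vy^2)
    t <- min(1, max(0, t))
    d <- sqrt((px - x1 - t * vx)^2 + (py - y1 - t * vy)^2)
    best <- min(best, d)
  }
  best
}

# tissue whose phenotype column is taken from the generator's ground truth,
# bypassing gating (used by spatial statistics tests)
truth_labeled_tissue <- function(spec) {
  tis <- generate_tissue(spec)
  tis$table$cells$phenotype <- tis$table$cells$true_phenotype
  tis
}

# disk-of-spots border fixture: dummy corner cells fix the raster grid over
# [-400, 400]^2; spots fill a disk of the given radius centred at 0
disk_border_fixture <- function(radius = 300, n_spots = 3000, s = 50,
                                seed = 1) {
  set.seed(seed)
  corners <- data.frame(sample_id = "d1",
                        x = c(-400, 400, -400, 400),
                        y = c(-400, -400, 400, 400),
                        CD8 = 0, CD11c = 0)
  tab <- cell_table(corners, channels = c("CD8", "CD11c"))
  tab$cells$phenotype <- "other"
  rr <- radius * sqrt(runif(n_spots))
  aa <- runif(n_spots, 0, 2 * pi)
  spots <- landmark_set("cea_spot",
                        points = cbind(rr * cos(aa), rr * sin(aa)),
                        sample_id = "d1")
  nt <- raster_neighborhoods(tab, landmarks = spots, r = s, s = s)
  # half-maximum threshold: half the typical deep-interior window count
  interior <- nt$nb$cea_spot[sqrt(nt$nb$x^2 + nt$nb$y^2) < radius - 2 * s]
  theta <- 0.5 * stats::median(interior)
  list(nt = nt, theta = theta, radius = radius, spots = spots)
}
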