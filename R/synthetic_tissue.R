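#' Synthetic tumor tissue specification
#'
#' Describes a 2D synthetic tumor section: a convex tumor nest (disk of
#' marker-positive cancer spots), an outer macrophage capsule (annulus),
#' straight vessel segments placed outside the deep nest, and cell
#' populations placed by rule — uniformly in tissue, inside the nest, in the
#' capsule ring, scattered about the nest boundary, or in perivascular
#' aggregates. Intensities per channel follow a bimodal model (bright
#' positive mode, dim negative mode) so that threshold gating separates
#' phenotypes cleanly; each generated cell records its true phenotype and
#' placement class as ground truth.
#'
#' Perivascular placement draws an anchor uniformly along a random vessel
#' segment (probability proportional to length) and displaces it along the
#' local vessel normal by the radial magnitude of an isotropic 2D Gaussian
#' with SD `sigma` — a Rayleigh(`sigma`) draw. The anchor is therefore the
#' nearest point of the segment, and the cell's distance to its vessel is
#' exactly Rayleigh distributed, which gives closed-form oracles for the
#' distance analyses.
#'
#' @param domain width and height of the tissue, um.
#' @param nest list with `center` (x, y) and `radius`, um; must lie inside
#'   the domain.
#' @param capsule_width width of the capsule annulus outside the nest, um.
#' @param vessels list with `n`, `length_mean`, `length_sd` (um); segments
#'   are placed with centers outside 0.8x the nest radius.
#' @param n_cea_spots number of tumor marker spots sampled uniformly in the
#'   nest.
#' @param populations named list (names = phenotype labels); each entry a
#'   list with `n`, `placement` (vector of placement classes, see Details),
#'   optional `weights` (mixture weights over placements) and optional
#'   `sigma` (um; for `near_boundary` and `perivascular`).
#' @param sample_id sample identifier.
#' @param seed integer seed; the whole tissue is drawn from one seeded RNG
#'   stream.
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(domain = c(1000, 1000),
                        nest = list(center = domain / 2, radius = 300),
                        capsule_width = 100,
                        vessels = list(n = 8, length_mean = 250,
                                       length_sd = 50),
                        n_cea_spots = 500,
                        populations = default_populations(),
                        sample_id = "s1",
                        seed = 1L) {
  stopifnot(length(domain) == 2, all(domain > 0), nest$radius > 0)
  if (any(nest$center - nest$radius < 0) ||
      any(nest$center + nest$radius > domain)) {
    stop("nest must lie inside the domain", call. = FALSE)
  }
  placements <- unlist(lapply(populations, `[[`, "placement"))
  known <- c("uniform_tissue", "inside_nest", "capsule_ring",
             "near_boundary", "perivascular")
  if (!all(placements %in% known)) {
    stop("unknown placement class: ",
         paste(setdiff(placements, known), collapse = ", "), call. = FALSE)
  }
  if ("capsule_ring" %in% placements && capsule_width <= 0) {
    stop("capsule_ring population requested but capsule_width <= 0",
         call. = FALSE)
  }
  if ("perivascular" %in% placements && vessels$n < 1) {
    stop("perivascular population requested but no vessels", call. = FALSE)
  }
  for (p in populations) {
    stopifnot(p$n >= 0)
    if (!is.null(p$sigma)) stopifnot(p$sigma > 0)
  }
  structure(list(domain = domain, nest = nest, capsule_width = capsule_width,
                 vessels = vessels, n_cea_spots = n_cea_spots,
                 populations = populations, sample_id = sample_id,
                 seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Default synthetic populations
#'
#' The standard population layout emulating a partially infiltrated tumor:
#' capsule-resident CD206+ macrophages, nest-resident non-activated
#' macrophages, perivascular DCs and activated macrophages, resource CD8 T
#' cells near vessels and the nest boundary, effector CD8 T cells that add an
#' inside-nest component growing with the infiltration parameter `phi`, and
#' a uniform background. Cell numbers of the perivascular/boundary T-cell and
#' activated myeloid pools scale with `phi`.
#'
#' @param phi infiltration parameter in \[0, 1\].
#' @return named list of population definitions for [tissue_spec()].
#' @export
default_populations <- function(phi = 0.5) {
  stopifnot(phi >= 0, phi <= 1)
  list(
    "CD206_Mf"      = list(n = 150, placement = "capsule_ring"),
    "MHCII-_Mf"     = list(n = 150, placement = "inside_nest"),
    "MHCII+_Mf"     = list(n = 60 + round(60 * phi),
                           placement = "perivascular", sigma = 15),
    "DC2"           = list(n = 80 + round(80 * phi),
                           placement = "perivascular", sigma = 12),
    "DC1"           = list(n = 15, placement = "perivascular", sigma = 12),
    "CD8_TCF1+PD1+" = list(n = 40 + round(80 * phi),
                           placement = c("perivascular", "near_boundary"),
                           weights = c(0.6, 0.4), sigma = 15),
    "CD8_TCF1-PD1+" = list(n = 60 + round(160 * phi),
                           placement = c("perivascular", "near_boundary",
                                         "inside_nest"),
                           weights = c(0.5 - 0.2 * phi, 0.35,
                                       0.15 + 0.2 * phi),
                           sigma = 15),
    "CD8_other"     = list(n = 20, placement = "uniform_tissue"),
    "CD4_T"         = list(n = 60, placement = "near_boundary", sigma = 30),
    "other"         = list(n = 150, placement = "uniform_tissue")
  )
}

#' Synthetic channel intensity model
#'
#' Positive markers are drawn from N(100, 12), negative markers from N(5, 3),
#' truncated at zero; PD-L1 is intermediate on activated myeloid cells. The
#' default gate threshold of 40 sits ~3 SD from both modes.
#'
#' @return named list: phenotype -> character vector of positive channels.
#' @keywords internal
positive_channels <- function() {
  list(
    "DC1"           = c("CD11c", "MHCII", "CD103"),
    "DC2"           = c("CD11c", "MHCII", "SIRPa"),
    "CD206_Mf"      = c("CD206"),
    "MHCII+_Mf"     = c("SIRPa", "MHCII"),
    "MHCII-_Mf"     = c("SIRPa"),
    "CD8_TCF1+PD1+" = c("CD3", "CD8", "TCF1", "PD1"),
    "CD8_TCF1-PD1+" = c("CD3", "CD8", "PD1"),
    "CD8_other"     = c("CD3", "CD8"),
    "CD4_T"         = c("CD3"),
    "other"         = character(0)
  )
}

tissue_channels <- function() {
  c("CD3", "CD8", "TCF1", "PD1", "CD11c", "MHCII", "CD103", "SIRPa",
    "CD206", "PDL1")
}

draw_intensities <- function(true_phenotype) {
  channels <- tissue_channels()
  pos <- positive_channels()
  n <- length(true_phenotype)
  out <- matrix(pmax(0, stats::rnorm(n * length(channels), 5, 3)),
                nrow = n, dimnames = list(NULL, channels))
  for (ph in unique(true_phenotype)) {
    idx <- which(true_phenotype == ph)
    for (ch in pos[[ph]]) {
      out[idx, ch] <- pmax(0, stats::rnorm(length(idx), 100, 12))
    }
    if (ph %in% c("MHCII+_Mf", "DC2")) {
      out[idx, "PDL1"] <- pmax(0, stats::rnorm(length(idx), 60, 10))
    }
  }
  out
}

rrayleigh <- function(n, sigma) sigma * sqrt(-2 * log(stats::runif(n)))

#' Rayleigh distribution function
#'
#' CDF of the radial magnitude of an isotropic 2D Gaussian with per-axis SD
#' `sigma`: `1 - exp(-q^2 / (2 sigma^2))`. Used as the closed-form oracle for
#' perivascular distance distributions.
#'
#' @param q quantiles (um).
#' @param sigma scale (um).
#' @return cumulative probabilities.
#' @export
prayleigh <- function(q, sigma) {
  ifelse(q < 0, 0, 1 - exp(-q^2 / (2 * sigma^2)))
}

# minimum distance between two segments (0 when they intersect)
seg_seg_distance <- function(a, b) {
  orient <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
  o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
  o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
  o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
  if (o1 != o2 && o3 != o4) return(0)
  pts_a <- rbind(a[1:2], a[3:4]); pts_b <- rbind(b[1:2], b[3:4])
  min(segment_distance_matrix(pts_a, rbind(b)),
      segment_distance_matrix(pts_b, rbind(a)))
}

place_vessels <- function(spec, clearance = 60) {
  v <- spec$vessels
  margin <- 100
  segs <- matrix(NA_real_, v$n, 4)
  i <- 0; tries <- 0
  while (i < v$n) {
    tries <- tries + 1
    if (tries > 20000) {
      stop("could not place ", v$n, " vessels with ", clearance,
           " um clearance in this domain", call. = FALSE)
    }
    cx <- stats::runif(1, margin, spec$domain[1] - margin)
    cy <- stats::runif(1, margin, spec$domain[2] - margin)
    # vessels ring the nest rather than pierce its core
    if (sqrt(sum((c(cx, cy) - spec$nest$center)^2)) <
        0.8 * spec$nest$radius) next
    len <- max(50, stats::rnorm(1, v$length_mean, v$length_sd))
    ang <- stats::runif(1, 0, pi)
    dx <- cos(ang) * len / 2
    dy <- sin(ang) * len / 2
    cand <- c(cx - dx, cy - dy, cx + dx, cy + dy)
    # pairwise clearance keeps perivascular displacements attributable to
    # one vessel, so their distance law stays exactly Rayleigh
    if (i > 0) {
      near <- vapply(seq_len(i), function(j) seg_seg_distance(segs[j, ],
                                                              cand),
                     numeric(1))
      if (any(near < clearance)) next
    }
    i <- i + 1
    segs[i, ] <- cand
  }
  segs
}

place_cells <- function(spec, placement, n, sigma, vessels) {
  ctr <- spec$nest$center
  R <- spec$nest$radius
  switch(placement,
    uniform_tissue = cbind(stats::runif(n, 0, spec$domain[1]),
                           stats::runif(n, 0, spec$domain[2])),
    inside_nest = {
      r <- R * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
    },
    capsule_ring = {
      r <- sqrt(stats::runif(n, R^2, (R + spec$capsule_width)^2))
      a <- stats::runif(n, 0, 2 * pi)
      cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
    },
    near_boundary = {
      a <- stats::runif(n, 0, 2 * pi)
      r <- R + stats::rnorm(n, 0, sigma %||% 25)
      cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
    },
    perivascular = {
      len <- sqrt((vessels[, 3] - vessels[, 1])^2 +
                  (vessels[, 4] - vessels[, 2])^2)
      seg <- sample.int(nrow(vessels), n, replace = TRUE, prob = len)
      t <- stats::runif(n)
      ax <- vessels[seg, 1] + t * (vessels[seg, 3] - vessels[seg, 1])
      ay <- vessels[seg, 2] + t * (vessels[seg, 4] - vessels[seg, 2])
      nx <- -(vessels[seg, 4] - vessels[seg, 2]) / len[seg]
      ny <- (vessels[seg, 3] - vessels[seg, 1]) / len[seg]
      side <- sample(c(-1, 1), n, replace = TRUE)
      d <- rrayleigh(n, sigma %||% 10)
      cbind(ax + side * nx * d, ay + side * ny * d)
    }
  )
}

#' Generate one synthetic tumor tissue
#'
#' @param spec a [tissue_spec()].
#' @return list with elements `table` (a [cell_table()] whose cells carry
#'   `true_phenotype` and `placement` ground-truth columns; `phenotype` is
#'   left unassigned for gating), `landmarks` (list with `cea_spot` points
#'   and `vessel` segments as [landmark_set()]s), and `spec`.
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  vessels <- place_vessels(spec)
  # tumor marker spots uniform in the nest
  n_spot <- spec$n_cea_spots
  r <- spec$nest$radius * sqrt(stats::runif(n_spot))
  a <- stats::runif(n_spot, 0, 2 * pi)
  cea <- cbind(spec$nest$center[1] + r * cos(a),
               spec$nest$center[2] + r * sin(a))
  pos <- list(); truth <- list(); place <- list()
  for (ph in names(spec$populations)) {
    p <- spec$populations[[ph]]
    if (p$n == 0) next
    pls <- p$placement
    draw <- if (length(pls) == 1) rep(pls, p$n) else {
      pls[sample.int(length(pls), p$n, replace = TRUE,
                     prob = p$weights %||% rep(1, length(pls)))]
    }
    xy <- matrix(NA_real_, p$n, 2)
    for (cl in unique(draw)) {
      idx <- which(draw == cl)
      xy[idx, ] <- place_cells(spec, cl, length(idx), p$sigma, vessels)
    }
    pos[[ph]] <- xy
    truth[[ph]] <- rep(ph, p$n)
    place[[ph]] <- draw
  }
  xy <- do.call(rbind, pos)
  true_ph <- unlist(truth, use.names = FALSE)
  mfi <- draw_intensities(true_ph)
  cells <- tibble::as_tibble(as.data.frame(mfi))
  cells <- cbind(tibble::tibble(sample_id = spec$sample_id,
                                x = xy[, 1], y = xy[, 2],
                                volume = pmax(10, stats::rnorm(nrow(xy),
                                                               250, 50)),
                                sphericity = stats::runif(nrow(xy), 0.6, 1)),
                 cells)
  cells$true_phenotype <- true_ph
  cells$placement <- unlist(place, use.names = FALSE)
  tab <- cell_table(cells, channels = tissue_channels(), dim = 2,
                    imaged_volume = prod(spec$domain) / 1e6)
  list(table = tab,
       landmarks = list(
         cea_spot = landmark_set("cea_spot", points = cea,
                                 sample_id = spec$sample_id),
         vessel = landmark_set("vessel_segment", segments = vessels,
                               sample_id = spec$sample_id)),
       spec = spec)
}

#' Synthetic cohort specification
#'
#' A cohort of `n_samples` synthetic tumors in which a per-sample
#' infiltration parameter `phi` in \[0, 1\] drives both the size of the
#' perivascular/boundary immune pools (via [default_populations()]) and the
#' tumor-volume fold change through the linear link
#' `fold_change = a - b * phi + N(0, sigma_fc)` (truncated below at 0.05).
#' Caliper length/width pairs at both timepoints are back-computed so that
#' the half length-times-width-squared volume formula reproduces the linked
#' fold change exactly.
#'
#' @param n_samples cohort size (>= 2).
#' @param a,b intercept and slope of the infiltration to fold-change link.
#'   `b = 0` disables the link (null cohort).
#' @param sigma_fc SD of the Gaussian noise on the fold change.
#' @param phi optional vector of infiltration parameters; default evenly
#'   spaced on \[0.05, 0.95\], emulating a cohort spanning untreated through
#'   combination-treated animals.
#' @param domain,nest_radius tissue geometry passed to each sample's
#'   [tissue_spec()].
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 20, a = 3, b = 2, sigma_fc = 0.25,
                        phi = NULL, domain = c(1000, 1000),
                        nest_radius = 300, seed = 1L) {
  stopifnot(n_samples >= 2, sigma_fc >= 0)
  if (is.null(phi)) phi <- seq(0.05, 0.95, length.out = n_samples)
  stopifnot(length(phi) == n_samples, all(phi >= 0), all(phi <= 1))
  structure(list(n_samples = n_samples, a = a, b = b, sigma_fc = sigma_fc,
                 phi = phi, domain = domain, nest_radius = nest_radius,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with outcome metadata
#'
#' @param spec a [cohort_spec()].
#' @return list with `samples` (list of [generate_tissue()] outputs, one per
#'   sample), `metadata` (a [sample_metadata()] tibble with caliper measures
#'   whose volume fold change equals the linked value), `phi`, `fold_change`
#'   and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  fc <- pmax(0.05, spec$a - spec$b * spec$phi +
               stats::rnorm(n, 0, spec$sigma_fc))
  v0 <- stats::runif(n, 100, 300)           # mm^3 at treatment start
  v1 <- fc * v0
  aspect <- 1.4                              # caliper length/width ratio
  w0 <- (2 * v0 / aspect)^(1 / 3); l0 <- aspect * w0
  w1 <- (2 * v1 / aspect)^(1 / 3); l1 <- aspect * w1
  seeds <- (spec$seed %% 100000L) * 10007L + seq_len(n) * 7919L
  ids <- sprintf("s%02d", seq_len(n))
  qs <- stats::quantile(spec$phi, c(0, .25, .5, .75, 1))
  groups <- if (anyDuplicated(qs)) {
    rep("cohort", n)
  } else {
    cut(spec$phi, breaks = qs,
        labels = c("vehicle", "aPD-L1", "TCB", "combo"),
        include.lowest = TRUE)
  }
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    ts <- tissue_spec(domain = spec$domain,
                      nest = list(center = spec$domain / 2,
                                  radius = spec$nest_radius),
                      populations = default_populations(spec$phi[i]),
                      sample_id = ids[i], seed = seeds[i])
    samples[[i]] <- generate_tissue(ts)
  }
  names(samples) <- ids
  meta <- sample_metadata(ids, as.character(groups), l0, w0, l1, w1)
  list(samples = samples, metadata = meta, phi = spec$phi,
       fold_change = fc, spec = spec)
}

#' Planted composition archetypes
#'
#' Generates neighborhood composition vectors from `k` planted archetypes for
#' validating region clustering: archetype `j` elevates its own block of 3
#' features by `separation / sqrt(6)` above a baseline of 1, giving pairwise
#' archetype L2 separation exactly `separation`; isotropic Gaussian noise of
#' per-feature SD `noise_sd` is added and values truncated at 0, so with the
#' default `noise_sd = 1` the separation is also expressed in within-class
#' SD units. The default separation of 6 within-class SDs reflects how
#' strongly distinct tissue regions (tumor nest vs T-cell-rich vs capsule)
#' differ in composition.
#'
#' @param n number of neighborhoods.
#' @param k number of archetypes (features = 3k).
#' @param separation pairwise archetype L2 distance (feature units).
#' @param noise_sd within-class per-feature SD.
#' @param seed integer seed.
#' @return list with `nt` (a neighborhood table whose count columns are the
#'   features) and `truth` (integer archetype labels).
#' @export
generate_archetypes <- function(n = 500, k = 3, separation = 6,
                                noise_sd = 1, seed = 1L) {
  set.seed(seed)
  p <- 3L * k
  c0 <- separation / sqrt(6)
  means <- matrix(1, k, p)
  for (j in seq_len(k)) means[j, (3 * j - 2):(3 * j)] <- 1 + c0
  truth <- sort(rep_len(seq_len(k), n))
  x <- means[truth, ] + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  x <- pmax(x, 0)
  colnames(x) <- sprintf("C%02d", seq_len(p))
  nb <- tibble::as_tibble(as.data.frame(x))
  nb <- cbind(tibble::tibble(sample_id = "arch",
                             x = rep(seq_len(n), each = 1) * 50, y = 0), nb)
  nt <- new_neighborhood_table(tibble::as_tibble(nb), r = 50, s = 50,
                               phenotypes = colnames(x),
                               landmarks = character(0), mode = "counts")
  list(nt = nt, truth = truth)
}
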