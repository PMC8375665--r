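#' Cluster neighborhoods into tissue regions
#'
#' Trains a self-organizing map on the per-window composition vectors (cell
#' counts plus landmark counts, standardized per feature) and merges the SOM
#' nodes into `k` regions by Ward-linkage hierarchical clustering of the
#' codebook vectors — a programmatic stand-in for the manual concatenation
#' and annotation of SOM clusters. Nodes never hit by training data inherit
#' the region of their nearest occupied node. Fully deterministic given
#' `seed`.
#'
#' @param nt a `nbhd_tbl` in counts mode.
#' @param k number of regions.
#' @param grid_dim SOM node grid (default 10 x 10).
#' @param epochs batch training sweeps (default 50).
#' @param features columns to cluster on; default all count columns,
#'   including landmark kinds (vessels and tumor spots are part of the
#'   composition space).
#' @param seed integer seed.
#' @return object of class `region_model`: the SOM fit, the node-to-region
#'   map, feature scaling parameters and settings.
#' @export
train_regions <- function(nt, k, grid_dim = c(10, 10), epochs = 50,
                          features = NULL, seed = 1L) {
  stopifnot(inherits(nt, "nbhd_tbl"), k >= 1)
  if (is.null(features)) features <- count_cols(nt)
  x <- as.matrix(nt$nb[, features, drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  som <- som_fit(xs, grid_dim = grid_dim, epochs = epochs, seed = seed)
  occupied <- sort(unique(som$bmu))
  if (k > length(occupied)) {
    stop("k = ", k, " exceeds the ", length(occupied),
         " occupied SOM nodes", call. = FALSE)
  }
  occ_region <- if (length(occupied) == 1) {
    1L
  } else {
    hc <- stats::hclust(stats::dist(som$codebook[occupied, , drop = FALSE]),
                        method = "ward.D2")
    stats::cutree(hc, k = k)
  }
  node_region <- integer(nrow(som$codebook))
  node_region[occupied] <- occ_region
  if (length(occupied) < nrow(som$codebook)) {
    vacant <- setdiff(seq_len(nrow(som$codebook)), occupied)
    d2 <- outer(rowSums(som$codebook[vacant, , drop = FALSE]^2),
                rowSums(som$codebook[occupied, , drop = FALSE]^2), "+") -
      2 * som$codebook[vacant, , drop = FALSE] %*%
        t(som$codebook[occupied, , drop = FALSE])
    node_region[vacant] <- occ_region[max.col(-d2, ties.method = "first")]
  }
  structure(list(som = som, node_region = node_region, k = k,
                 features = features, center = center, scale = scale,
                 seed = seed),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat("<region_model> ", x$k, " regions from a ",
      paste(x$som$grid_dim, collapse = "x"), " SOM on ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}

#' Assign neighborhoods to regions
#'
#' Maps each window to its best-matching SOM node and thence to that node's
#' region. Re-assigning the training data reproduces the training
#' assignment.
#'
#' @param nt a `nbhd_tbl` with the model's feature columns.
#' @param model a [train_regions()] model.
#' @return `nt` with a `region` column (`"R1"` ... `"Rk"`).
#' @export
assign_regions <- function(nt, model) {
  stopifnot(inherits(nt, "nbhd_tbl"), inherits(model, "region_model"))
  missing <- setdiff(model$features, names(nt$nb))
  if (length(missing) > 0) {
    stop("feature mismatch: table lacks ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(nt$nb[, model$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  bmu <- som_map(model$som$codebook, xs)
  nt$nb$region <- paste0("R", model$node_region[bmu])
  nt
}

#' Region composition heatmap, prevalence, and classes
#'
#' Summarizes assigned regions the way region analyses are reported: a
#' heatmap of fold changes (mean count per window inside the region divided
#' by the overall mean count per window, per label), per-sample region
#' prevalence (fraction of each sample's windows in each region; rows sum to
#' 1), and a rule-based region class — `t_cell_rich` when the mean fold
#' change of the infiltrating CD8 subsets reaches `tau_t`, `tumor` when the
#' tumor-spot fold change reaches `tau_c` without the CD8 enrichment,
#' `other` otherwise. The mean (not the sum) is compared with `tau_t` so
#' that the no-enrichment baseline is 1 regardless of how many CD8 subsets
#' are listed; the default subsets are the PD1+ resource and effector pools
#' that define T-cell infiltration, leaving ungated background CD8 cells
#' out.
#'
#' @param nt a `nbhd_tbl` with regions assigned.
#' @param tau_t threshold on the mean CD8-subset fold change (default 2).
#' @param tau_c threshold on the tumor-spot fold change (default 2).
#' @param cd8_labels the CD8 subset columns.
#' @param tumor_label the tumor-spot landmark column.
#' @return object of class `region_summary`: `heatmap` (region x label fold
#'   changes), `prevalence` (sample x region), `region_class`, `n_windows`.
#' @export
region_summary <- function(nt, tau_t = 2, tau_c = 2,
                           cd8_labels = c("CD8_TCF1+PD1+", "CD8_TCF1-PD1+"),
                           tumor_label = "cea_spot") {
  stopifnot(inherits(nt, "nbhd_tbl"))
  if (!"region" %in% names(nt$nb)) {
    stop("regions not assigned; run assign_regions()", call. = FALSE)
  }
  nb <- nt$nb
  labels <- count_cols(nt)
  regions <- sort(unique(nb$region))
  x <- as.matrix(nb[, labels, drop = FALSE])
  overall <- colMeans(x)
  heat <- t(vapply(regions, function(rg) {
    colMeans(x[nb$region == rg, , drop = FALSE])
  }, numeric(length(labels))))
  heat <- sweep(heat, 2, ifelse(overall > 0, overall, NA), "/")
  dimnames(heat) <- list(regions, labels)
  samples <- unique(nb$sample_id)
  prev <- matrix(NA_real_, length(samples), length(regions),
                 dimnames = list(samples, regions))
  for (sid in samples) {
    tab <- table(factor(nb$region[nb$sample_id == sid], levels = regions))
    prev[sid, ] <- as.numeric(tab) / sum(tab)
  }
  cd8_sum <- rowMeans(heat[, intersect(cd8_labels, labels), drop = FALSE],
                      na.rm = TRUE)
  tumor_fc <- if (tumor_label %in% labels) heat[, tumor_label] else
    rep(0, length(regions))
  tumor_fc[is.na(tumor_fc)] <- 0
  region_class <- ifelse(cd8_sum >= tau_t, "t_cell_rich",
                         ifelse(tumor_fc >= tau_c, "tumor", "other"))
  names(region_class) <- regions
  structure(list(heatmap = heat, prevalence = prev,
                 region_class = region_class,
                 n_windows = nrow(nb), tau_t = tau_t, tau_c = tau_c),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat("<region_summary> ", nrow(x$heatmap), " regions, ",
      nrow(x$prevalence), " samples\n", sep = "")
  cat("classes:", paste(names(x$region_class), x$region_class,
                        sep = "=", collapse = ", "), "\n")
  print(round(x$heatmap, 2))
  invisible(x)
}

#' Nonlinear 2D embedding of neighborhoods
#'
#' UMAP embedding of the standardized window composition vectors, for
#' visualizing region structure (points colored by region). Seeded and run
#' single-threaded so coordinates are reproducible.
#'
#' @param nt a `nbhd_tbl`.
#' @param features columns to embed; default all count columns.
#' @param n_neighbors UMAP neighborhood size (capped at n - 1).
#' @param seed integer seed.
#' @return tibble with `sample_id`, `umap1`, `umap2` and `region` when
#'   present.
#' @export
embed_neighborhoods <- function(nt, features = NULL, n_neighbors = 15,
                                seed = 1L) {
  stopifnot(inherits(nt, "nbhd_tbl"))
  if (is.null(features)) features <- count_cols(nt)
  x <- as.matrix(nt$nb[, features, drop = FALSE])
  if (nrow(x) < 10) stop("too few neighborhoods to embed (need >= 10)",
                         call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd); scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  set.seed(seed)
  emb <- uwot::umap(xs, n_neighbors = min(n_neighbors, nrow(x) - 1),
                    n_threads = 1, n_sgd_threads = 1, batch = TRUE)
  out <- tibble::tibble(sample_id = nt$nb$sample_id,
                        umap1 = emb[, 1], umap2 = emb[, 2])
  if ("region" %in% names(nt$nb)) out$region <- nt$nb$region
  out
}
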