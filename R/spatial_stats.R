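#' Significance of a Pearson correlation via the t transform
#'
#' Two-sided p-value from Student's t distribution for the transformed
#' correlation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom; `|r| = 1` gives p = 0 and undefined r gives NA.
#'
#' @param r Pearson correlation coefficient(s).
#' @param n number of observations.
#' @return two-sided p-value(s).
#' @export
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  t <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p[ok][abs(r[ok]) >= 1] <- 0
  p
}

#' Pairwise spatial correlation of neighborhood counts
#'
#' Pearson correlation between the per-window counts of every pair of cell
#' populations (and landmark kinds), pooled across all samples or computed
#' within treatment groups — positive values flag populations that
#' co-localize in the same windows, negative values populations that avoid
#' one another. Significance uses the t transform of the correlation
#' ([cor_pvalue()]). Zero-variance columns give NA.
#'
#' @param nt a `nbhd_tbl`.
#' @param grouping `"all"` (pool all neighborhoods) or `"per-group"`.
#' @param metadata a [sample_metadata()] tibble, required for `"per-group"`.
#' @param labels columns to correlate; default all count columns.
#' @param p_adjust optional method for [stats::p.adjust()] applied to the
#'   off-diagonal p-values (e.g. `"BH"`); default none.
#' @return object of class `cor_matrix` with elements `r`, `p`, `n`,
#'   `labels` — or a named list of such objects for `"per-group"`.
#' @export
correlation_matrix <- function(nt, grouping = c("all", "per-group"),
                               metadata = NULL, labels = NULL,
                               p_adjust = NULL) {
  stopifnot(inherits(nt, "nbhd_tbl"))
  grouping <- match.arg(grouping)
  if (is.null(labels)) labels <- count_cols(nt)
  if (length(labels) < 2) stop("need at least 2 labels", call. = FALSE)
  if (grouping == "per-group") {
    if (is.null(metadata)) {
      stop("per-group correlation needs sample metadata", call. = FALSE)
    }
    grp <- metadata$group[match(nt$nb$sample_id, metadata$sample_id)]
    out <- lapply(split(seq_len(nrow(nt$nb)), grp), function(idx) {
      sub <- nt
      sub$nb <- nt$nb[idx, , drop = FALSE]
      correlation_matrix(sub, "all", labels = labels, p_adjust = p_adjust)
    })
    return(out)
  }
  x <- as.matrix(nt$nb[, labels, drop = FALSE])
  n <- nrow(x)
  if (n < 3) stop("insufficient data: need >= 3 neighborhoods", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  p <- matrix(cor_pvalue(as.vector(r), n), length(labels),
              dimnames = dimnames(r))
  diag(p) <- NA
  if (!is.null(p_adjust)) {
    off <- upper.tri(p)
    p[off] <- stats::p.adjust(p[off], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, n = n, labels = labels),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat("<cor_matrix> ", length(x$labels), " labels, n = ", x$n,
      " neighborhoods\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Per-neighborhood channel intensity bands
#'
#' Adds pseudo-label count columns for a channel (e.g. PD-L1) discretized
#' into bands by quantiles of the per-window mean MFI: each band column holds
#' the window's cell count if the window's mean intensity falls in that band,
#' else 0, so bands enter [correlation_matrix()] like cell populations.
#'
#' @param nt a `nbhd_tbl` in counts mode.
#' @param table the [cell_table()] the windows were rastered from.
#' @param channel channel name.
#' @param probs quantile break points (default intermediate/high at the 0.5
#'   and 0.9 quantiles of window mean MFI).
#' @return `nt` with columns `<channel>_int` and `<channel>_hi` appended.
#' @export
add_channel_bands <- function(nt, table, channel, probs = c(0.5, 0.9)) {
  stopifnot(inherits(nt, "nbhd_tbl"), inherits(table, "cell_table"),
            channel %in% table$channels)
  cells <- table$cells
  meanmfi <- rep(NA_real_, nrow(nt$nb))
  total <- rowSums(as.matrix(nt$nb[, nt$phenotypes, drop = FALSE]))
  for (sid in unique(nt$nb$sample_id)) {
    ni <- which(nt$nb$sample_id == sid)
    cs <- cells[cells$sample_id == sid, , drop = FALSE]
    centers <- as.matrix(nt$nb[ni, c("x", "y")])
    for (b in seq_along(ni)) {
      d2 <- (cs$x - centers[b, 1])^2 + (cs$y - centers[b, 2])^2
      inside <- d2 <= nt$r^2
      if (any(inside)) meanmfi[ni[b]] <- mean(cs[[channel]][inside])
    }
  }
  breaks <- stats::quantile(meanmfi, probs, na.rm = TRUE)
  int_band <- !is.na(meanmfi) & meanmfi >= breaks[1] & meanmfi < breaks[2]
  hi_band <- !is.na(meanmfi) & meanmfi >= breaks[2]
  nt$nb[[paste0(channel, "_int")]] <- ifelse(int_band, total, 0)
  nt$nb[[paste0(channel, "_hi")]] <- ifelse(hi_band, total, 0)
  nt$landmarks <- c(nt$landmarks, paste0(channel, "_int"),
                    paste0(channel, "_hi"))
  nt
}

#' Fit the tumor border from marker-spot clustering
#'
#' Thresholds the per-window tumor-spot counts on the raster grid (windows
#' with at least `theta` spots are tumor), keeps the largest 4-connected
#' component, fills single-node holes, and traces the boundary as the closed
#' contour of grid-cell edges between tumor and non-tumor cells (each grid
#' node owning a square cell of side `s`).
#'
#' @param nt a `nbhd_tbl` containing a tumor-spot landmark count column
#'   (default `"cea_spot"`), for a single sample.
#' @param theta minimum spot count per window (default 1).
#' @param landmark name of the spot count column.
#' @param sample_id sample to fit; required when `nt` holds several.
#' @return object of class `border_model`: grid axes, logical mask,
#'   `segments` (m x 4 matrix of boundary edges, um) and parameters.
#' @export
fit_border <- function(nt, theta = 1, landmark = "cea_spot",
                       sample_id = NULL) {
  stopifnot(inherits(nt, "nbhd_tbl"))
  if (!landmark %in% names(nt$nb)) {
    stop("no '", landmark, "' counts in the neighborhood table",
         call. = FALSE)
  }
  nb <- nt$nb
  if (!is.null(sample_id)) nb <- nb[nb$sample_id == sample_id, ,
                                    drop = FALSE]
  if (length(unique(nb$sample_id)) > 1) {
    stop("border is fitted per sample; supply sample_id", call. = FALSE)
  }
  s <- nt$s
  gx <- sort(unique(nb$x)); gy <- sort(unique(nb$y))
  ix <- match(nb$x, gx); iy <- match(nb$y, gy)
  cnt <- matrix(0, length(gx), length(gy))
  cnt[cbind(ix, iy)] <- nb[[landmark]]
  mask <- if (theta <= 0) cnt > 0 else cnt >= theta
  if (!any(mask)) {
    stop("no windows reach theta = ", theta, "; lower the threshold",
         call. = FALSE)
  }
  comp <- connected_components(mask)
  sizes <- tabulate(comp[comp > 0])
  if (length(sizes) > 1) {
    message("border: keeping largest of ", length(sizes),
            " connected components")
  }
  mask <- comp == which.max(sizes)
  mask <- fill_single_holes(mask)
  segs <- mask_contour(mask, gx, gy, s)
  structure(list(gx = gx, gy = gy, mask = mask, segments = segs,
                 s = s, theta = theta,
                 sample_id = unique(nb$sample_id)),
            class = "border_model")
}

# 4-connected components by iterative label propagation
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
        if (ni < 1 || nj < 1 || ni > nrow(mask) || nj > ncol(mask)) next
        if (mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  lab
}

fill_single_holes <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  nb4 <- pad[1:n, 2:(m + 1)] + pad[3:(n + 2), 2:(m + 1)] +
    pad[2:(n + 1), 1:m] + pad[2:(n + 1), 3:(m + 2)]
  mask | (nb4 == 4)
}

# boundary of the union of grid squares (side s) centered on masked nodes
mask_contour <- function(mask, gx, gy, s) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  segs <- list()
  idx <- which(mask, arr.ind = TRUE)
  h <- s / 2
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    cx <- gx[i]; cy <- gy[j]
    if (!pad[i, j + 1])     segs[[length(segs) + 1]] <-
        c(cx - h, cy - h, cx - h, cy + h)   # left edge
    if (!pad[i + 2, j + 1]) segs[[length(segs) + 1]] <-
        c(cx + h, cy - h, cx + h, cy + h)   # right edge
    if (!pad[i + 1, j])     segs[[length(segs) + 1]] <-
        c(cx - h, cy - h, cx + h, cy - h)   # bottom edge
    if (!pad[i + 1, j + 2]) segs[[length(segs) + 1]] <-
        c(cx - h, cy + h, cx + h, cy + h)   # top edge
  }
  do.call(rbind, segs)
}

#' @export
print.border_model <- function(x, ...) {
  cat("<border_model> sample ", x$sample_id, ": ", sum(x$mask),
      " tumor windows, ", nrow(x$segments), " boundary edges (theta=",
      x$theta, ", s=", x$s, " um)\n", sep = "")
  invisible(x)
}

#' Signed distance of cells to the tumor border
#'
#' Unsigned distance is the exact Euclidean distance to the nearest boundary
#' edge of the fitted border; the sign is positive inside the tumor mask and
#' negative outside (cells on the boundary get 0), so infiltration depth
#' reads directly off the profile.
#'
#' @param cells a [cell_table()], a data frame with `x`, `y`, or an n x 2
#'   matrix of positions (um).
#' @param border a [fit_border()] model.
#' @return tibble with columns `x`, `y`, `distance` (um) plus any phenotype
#'   column present in the input; class `distance_profile`, attribute
#'   `reference = "tumor_border"`.
#' @export
signed_distance_to_border <- function(cells, border) {
  stopifnot(inherits(border, "border_model"))
  pos <- as_positions(cells)
  d <- segment_distance_matrix(pos$xy, border$segments)
  dmin <- apply(d, 1, min)
  # inside test: the grid cell the point falls in (nearest node's square)
  ii <- pmin(pmax(round((pos$xy[, 1] - border$gx[1]) / border$s) + 1, 1),
             length(border$gx))
  jj <- pmin(pmax(round((pos$xy[, 2] - border$gy[1]) / border$s) + 1, 1),
             length(border$gy))
  inside <- border$mask[cbind(ii, jj)]
  out <- tibble::tibble(x = pos$xy[, 1], y = pos$xy[, 2],
                        distance = ifelse(inside, dmin, -dmin))
  if (!is.null(pos$phenotype)) out$phenotype <- pos$phenotype
  attr(out, "reference") <- "tumor_border"
  class(out) <- c("distance_profile", class(out))
  out
}

#' Distance of cells to the nearest landmark
#'
#' Exact minimum point-to-point (spot, vessel-point) or point-to-segment
#' (vessel centreline) Euclidean distance from every cell to a landmark set.
#'
#' @param cells as in [signed_distance_to_border()].
#' @param landmarks a nonempty [landmark_set()].
#' @return tibble with `x`, `y`, `distance` (um, >= 0) and `phenotype` when
#'   available; class `distance_profile`.
#' @export
nearest_distance <- function(cells, landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pos <- as_positions(cells)
  if (landmarks$kind == "vessel_segment") {
    if (nrow(landmarks$segments) == 0) stop("empty landmark set",
                                            call. = FALSE)
    d <- segment_distance_matrix(pos$xy, landmarks$segments)
  } else {
    if (nrow(landmarks$points) == 0) stop("empty landmark set",
                                          call. = FALSE)
    d <- sqrt(outer(pos$xy[, 1], landmarks$points[, 1], "-")^2 +
              outer(pos$xy[, 2], landmarks$points[, 2], "-")^2)
  }
  out <- tibble::tibble(x = pos$xy[, 1], y = pos$xy[, 2],
                        distance = apply(d, 1, min))
  if (!is.null(pos$phenotype)) out$phenotype <- pos$phenotype
  attr(out, "reference") <- paste0("nearest_", landmarks$kind)
  class(out) <- c("distance_profile", class(out))
  out
}

as_positions <- function(cells) {
  if (inherits(cells, "cell_table")) {
    list(xy = cbind(cells$cells$x, cells$cells$y),
         phenotype = cells$cells[["phenotype"]])
  } else if (is.data.frame(cells)) {
    list(xy = cbind(cells$x, cells$y), phenotype = cells[["phenotype"]])
  } else {
    list(xy = as.matrix(cells), phenotype = NULL)
  }
}

#' Summarize a distance profile by phenotype
#'
#' @param profile a `distance_profile`.
#' @param proximal_um threshold for the "highly proximal" fraction (default
#'   25 um).
#' @param probs quantiles to report.
#' @return tibble with one row per phenotype (or a single `all` row): n,
#'   quantiles, mean, and the fraction of cells closer than `proximal_um`.
#' @export
summarize_distances <- function(profile, proximal_um = 25,
                                probs = c(0.25, 0.5, 0.75)) {
  ph <- profile$phenotype %||% rep("all", nrow(profile))
  rows <- lapply(split(profile$distance, ph), function(d) {
    q <- stats::quantile(d, probs)
    tibble::tibble(n = length(d), mean = mean(d),
                   q25 = q[[1]], median = q[[2]], q75 = q[[3]],
                   frac_proximal = mean(d < proximal_um))
  })
  out <- do.call(rbind, rows)
  out <- cbind(tibble::tibble(phenotype = names(rows)), out)
  tibble::as_tibble(out)
}
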