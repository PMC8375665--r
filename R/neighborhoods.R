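#' Neighborhood table constructor (internal)
#'
#' @param nb tibble with columns `sample_id`, `x`, `y` (neighborhood
#'   centers), one count column per phenotype and per landmark kind, and
#'   optionally `region`.
#' @param r neighborhood radius, um.
#' @param s raster spacing, um.
#' @param phenotypes,landmarks names of the count columns.
#' @param mode one of `"counts"`, `"density"`, `"composition"`.
#' @return object of class `nbhd_tbl`.
#' @keywords internal
new_neighborhood_table <- function(nb, r, s, phenotypes, landmarks,
                                   mode = "counts") {
  structure(list(nb = tibble::as_tibble(nb), r = r, s = s,
                 phenotypes = phenotypes, landmarks = landmarks,
                 mode = mode),
            class = "nbhd_tbl")
}

#' @export
print.nbhd_tbl <- function(x, ...) {
  cat("<nbhd_tbl> ", nrow(x$nb), " neighborhoods (r=", x$r, " um, s=", x$s,
      " um, ", x$mode, "), ", length(unique(x$nb$sample_id)),
      " sample(s)\n", sep = "")
  print(utils::head(x$nb, 5))
  invisible(x)
}

count_cols <- function(nt) c(nt$phenotypes, nt$landmarks)

#' Raster-scanned spatial neighborhoods
#'
#' Scans a regular grid of window centers over each sample's cell bounding
#' box (spacing `s`, grid anchored at the bounding-box corner) and counts,
#' per center, the cells of each phenotype and the landmarks of each kind
#' within Euclidean distance `r` (closed ball, so a cell at exactly `r` is
#' included). Windows overlap when `s < 2r`; with `s = 2r` every cell falls
#' in at most one window. Point landmarks are counted like cells; segment
#' landmarks (vessels) are counted once per window whose center lies within
#' `r` of the segment. Windows containing neither cells nor landmarks are
#' dropped by default.
#'
#' @param table a [cell_table()] with phenotypes assigned.
#' @param landmarks a single [landmark_set()] or list of them (matched to
#'   samples by their `sample_id`).
#' @param r window radius, um (default 50).
#' @param s raster spacing, um (default `r`).
#' @param drop_empty drop windows with zero cells and zero landmarks.
#' @param phenotypes phenotype levels to count; default the labels present.
#' @return a neighborhood table (`nbhd_tbl`) in `"counts"` mode.
#' @export
raster_neighborhoods <- function(table, landmarks = list(), r = 50, s = r,
                                 drop_empty = TRUE, phenotypes = NULL) {
  stopifnot(inherits(table, "cell_table"), r > 0, s > 0)
  cells <- table$cells
  if (nrow(cells) == 0) {
    warning("no cells; returning empty neighborhood table")
    return(new_neighborhood_table(
      tibble::tibble(sample_id = character(), x = numeric(), y = numeric()),
      r, s, character(0), character(0)))
  }
  if (!"phenotype" %in% names(cells) || all(is.na(cells$phenotype))) {
    stop("cells are not labeled; run apply_gates() first", call. = FALSE)
  }
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  lm_kinds <- unique(vapply(landmarks, `[[`, character(1), "kind"))
  lm_kinds <- sub("^vessel_(point|segment)$", "vessel", lm_kinds)
  lm_kinds <- unique(lm_kinds)
  out <- list()
  for (sid in unique(cells$sample_id)) {
    cs <- cells[cells$sample_id == sid, , drop = FALSE]
    gx <- seq(min(cs$x), max(cs$x) + s - 1e-9, by = s)
    gy <- seq(min(cs$y), max(cs$y) + s - 1e-9, by = s)
    centers <- cbind(x = rep(gx, times = length(gy)),
                     y = rep(gy, each = length(gx)))
    counts <- matrix(0L, nrow(centers), length(phenotypes),
                     dimnames = list(NULL, phenotypes))
    for (ph in phenotypes) {
      sel <- which(cs$phenotype == ph)
      if (length(sel) == 0) next
      counts[, ph] <- count_within(centers, cs$x[sel], cs$y[sel], r)
    }
    lmc <- matrix(0L, nrow(centers), length(lm_kinds),
                  dimnames = list(NULL, lm_kinds))
    for (l in landmarks) {
      if (!identical(l$sample_id, sid)) next
      kind <- sub("^vessel_(point|segment)$", "vessel", l$kind)
      if (l$kind == "vessel_segment") {
        d <- segment_distance_matrix(centers, l$segments)
        lmc[, kind] <- lmc[, kind] + as.integer(rowSums(d <= r))
      } else {
        lmc[, kind] <- lmc[, kind] +
          count_within(centers, l$points[, 1], l$points[, 2], r)
      }
    }
    nb <- tibble::tibble(sample_id = sid, x = centers[, 1], y = centers[, 2])
    nb <- cbind(nb, tibble::as_tibble(as.data.frame(counts)),
                tibble::as_tibble(as.data.frame(lmc)))
    if (drop_empty) {
      keep <- rowSums(counts) > 0 | (length(lm_kinds) > 0 & rowSums(lmc) > 0)
      nb <- nb[keep, , drop = FALSE]
    }
    out[[sid]] <- tibble::as_tibble(nb)
  }
  new_neighborhood_table(do.call(rbind, out), r, s, phenotypes, lm_kinds)
}

# closed-ball point counting on a center grid; exact, vectorized in blocks
count_within <- function(centers, px, py, r) {
  n <- nrow(centers)
  res <- integer(n)
  block <- max(1L, floor(2e6 / max(1, length(px))))
  r2 <- r^2
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- outer(centers[idx, 1], px, "-")^2 +
      outer(centers[idx, 2], py, "-")^2
    res[idx] <- as.integer(rowSums(d2 <= r2))
  }
  res
}

# exact point-to-segment distances: points (n x 2) vs segments (m x 4)
segment_distance_matrix <- function(points, segments) {
  n <- nrow(points); m <- nrow(segments)
  d <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    x1 <- segments[j, 1]; y1 <- segments[j, 2]
    x2 <- segments[j, 3]; y2 <- segments[j, 4]
    vx <- x2 - x1; vy <- y2 - y1
    len2 <- vx^2 + vy^2
    t <- ((points[, 1] - x1) * vx + (points[, 2] - y1) * vy) / len2
    t <- pmin(1, pmax(0, t))
    d[, j] <- sqrt((points[, 1] - (x1 + t * vx))^2 +
                   (points[, 2] - (y1 + t * vy))^2)
  }
  d
}

#' Normalize neighborhood counts
#'
#' Converts raw window counts to densities (count per window area, um^-2; or
#' per window volume in 3D) or to composition fractions (each row divided by
#' its total cell count; landmark columns are excluded from the composition
#' denominator). Both transforms are invertible: the information needed to
#' recover raw counts (window area, row totals) is retained.
#'
#' @param nt a `nbhd_tbl` in `"counts"` mode.
#' @param mode `"density"` or `"composition"` (or `"counts"`, a no-op).
#' @return a transformed `nbhd_tbl`.
#' @export
normalize_neighborhoods <- function(nt, mode = c("density", "composition",
                                                 "counts")) {
  stopifnot(inherits(nt, "nbhd_tbl"))
  mode <- match.arg(mode)
  if (mode == "counts") return(nt)
  if (nt$mode != "counts") {
    stop("can only normalize a table in 'counts' mode", call. = FALSE)
  }
  cols <- count_cols(nt)
  if (mode == "density") {
    area <- pi * nt$r^2
    for (col in cols) nt$nb[[col]] <- nt$nb[[col]] / area
  } else {
    tot <- rowSums(as.matrix(nt$nb[, nt$phenotypes, drop = FALSE]))
    nt$nb$.total <- tot
    for (col in nt$phenotypes) {
      nt$nb[[col]] <- ifelse(tot > 0, nt$nb[[col]] / tot, 0)
    }
  }
  nt$mode <- mode
  nt
}

#' Invert [normalize_neighborhoods()]
#'
#' @param nt a normalized `nbhd_tbl`.
#' @return the table restored to `"counts"` mode.
#' @export
denormalize_neighborhoods <- function(nt) {
  stopifnot(inherits(nt, "nbhd_tbl"))
  if (nt$mode == "counts") return(nt)
  if (nt$mode == "density") {
    area <- pi * nt$r^2
    for (col in count_cols(nt)) {
      nt$nb[[col]] <- round(nt$nb[[col]] * area)
    }
  } else {
    for (col in nt$phenotypes) {
      nt$nb[[col]] <- round(nt$nb[[col]] * nt$nb$.total)
    }
    nt$nb$.total <- NULL
  }
  nt$mode <- "counts"
  nt
}

#' Write a neighborhood table to CSV
#' @param nt a `nbhd_tbl`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighborhoods <- function(nt, path) {
  readr::write_csv(nt$nb, path, progress = FALSE)
  invisible(path)
}
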