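#' Construct a cell-object table
#'
#' The universal currency of the pipeline: one row per segmented cell object,
#' with its sample of origin, centroid position in micrometres, per-channel
#' mean fluorescence intensities (MFI), and optional morphology columns
#' (volume in um^3, sphericity in \[0, 1\]) as exported by image-segmentation
#' software.
#'
#' @param cells data frame with columns `sample_id`, `x`, `y` (and `z` for 3D
#'   tables), one numeric column per channel, and optionally `volume`,
#'   `sphericity`, `phenotype`. Extra columns are preserved.
#' @param channels character vector naming the channel (MFI) columns. If
#'   `NULL`, all numeric columns other than the reserved ones are taken as
#'   channels.
#' @param dim spatial dimensionality, 2 (tissue sections, the default) or 3.
#' @param imaged_volume imaged area in mm^2 (2D) or volume in mm^3 (3D);
#'   either a single value shared by all samples or a named vector keyed by
#'   `sample_id`. Required by [cell_density()], otherwise optional.
#' @return An object of class `cell_table`: a list with elements `cells`
#'   (tibble), `channels`, `dim` and `imaged_volume`.
#' @examples
#' ct <- cell_table(data.frame(sample_id = "s1", x = c(10, 20), y = c(5, 5),
#'                             CD8 = c(120, 3), CD3 = c(110, 2)))
#' ct$channels
#' @export
cell_table <- function(cells, channels = NULL, dim = 2, imaged_volume = NULL) {
  stopifnot(is.data.frame(cells), dim %in% c(2L, 3L))
  cells <- tibble::as_tibble(cells)
  required <- c("sample_id", "x", "y", if (dim == 3) "z")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  reserved <- c("sample_id", "x", "y", "z", "volume", "sphericity",
                "phenotype", "true_phenotype", "placement")
  if (is.null(channels)) {
    channels <- names(cells)[vapply(cells, is.numeric, logical(1))]
    channels <- setdiff(channels, reserved)
  } else {
    missing <- setdiff(channels, names(cells))
    if (length(missing) > 0) {
      stop("channel column(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  obj <- structure(
    list(cells = cells, channels = channels, dim = as.integer(dim),
         imaged_volume = imaged_volume),
    class = "cell_table"
  )
  validate_cell_table(obj)
  obj
}

validate_cell_table <- function(x) {
  cells <- x$cells
  pos_cols <- c("x", "y", if (x$dim == 3) "z")
  for (col in pos_cols) {
    if (!is.numeric(cells[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(cells[[col]]))))[1]
      stop("non-numeric position in column '", col, "' at row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
    if (any(!is.finite(cells[[col]]))) {
      stop("non-finite position in column '", col, "' at row ",
           which(!is.finite(cells[[col]]))[1], call. = FALSE)
    }
  }
  for (ch in x$channels) {
    v <- cells[[ch]]
    if (!is.numeric(v)) stop("channel '", ch, "' is not numeric", call. = FALSE)
    if (any(v < 0, na.rm = TRUE)) {
      stop("channel '", ch, "' violates the nonnegative-MFI invariant at row ",
           which(v < 0)[1], call. = FALSE)
    }
  }
  if ("sphericity" %in% names(cells)) {
    s <- cells$sphericity
    if (any(s < 0 | s > 1, na.rm = TRUE)) {
      stop("sphericity outside [0, 1] at row ", which(s < 0 | s > 1)[1],
           call. = FALSE)
    }
  }
  if (!is.null(x$imaged_volume) && any(x$imaged_volume <= 0)) {
    stop("imaged_volume must be positive", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x$cells), " cells, ",
      length(unique(x$cells$sample_id)), " sample(s), ",
      length(x$channels), " channels, ", x$dim, "D\n", sep = "")
  if (!is.null(x$imaged_volume)) {
    cat("  imaged ", if (x$dim == 2) "area (mm^2): " else "volume (mm^3): ",
        paste(signif(x$imaged_volume, 4), collapse = ", "), "\n", sep = "")
  }
  print(utils::head(x$cells, 5))
  invisible(x)
}

#' Read a cell-object table from CSV
#'
#' Reads a comma-separated export (UTF-8, one header row) of segmented cell
#' objects. Column naming varies between segmentation pipelines, so an
#' optional schema maps the file's column names onto the standard ones;
#' unmapped extra columns are preserved.
#'
#' @param path path to a CSV file.
#' @param schema optional column mapping: a named list with entries `sample`,
#'   `x`, `y` (optionally `z`, `volume`, `sphericity`, `phenotype`) giving the
#'   corresponding column names in the file, and optionally `channels`, a
#'   character vector of channel columns. May also be a path to a YAML file
#'   holding that list. `NULL` assumes standard names.
#' @param dim 2 or 3.
#' @param imaged_volume passed to [cell_table()].
#' @return a [cell_table()].
#' @export
read_cell_table <- function(path, schema = NULL, dim = 2,
                            imaged_volume = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    std <- c(sample = "sample_id", x = "x", y = "y", z = "z",
             volume = "volume", sphericity = "sphericity",
             phenotype = "phenotype")
    for (key in intersect(names(std), names(schema))) {
      src <- schema[[key]]
      if (!src %in% names(raw)) {
        stop("schema maps '", key, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- std[[key]]
    }
    channels <- schema$channels
  } else {
    channels <- NULL
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, names(raw))
    if (length(missing) > 0) {
      stop("schema names missing channel column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (col in intersect(c("x", "y", if (dim == 3) "z"), names(raw))) {
    if (!is.numeric(raw[[col]])) {
      num <- suppressWarnings(as.numeric(raw[[col]]))
      if (any(is.na(num) & !is.na(raw[[col]]))) {
        stop("non-numeric position value in column '", col, "' at row ",
             which(is.na(num) & !is.na(raw[[col]]))[1], call. = FALSE)
      }
      raw[[col]] <- num
    }
  }
  cell_table(raw, channels = channels, dim = dim,
             imaged_volume = imaged_volume)
}

#' Write a cell-object table to CSV
#'
#' Inverse of [read_cell_table()] under standard column names: the written
#' file round-trips losslessly (positions and MFIs at full double precision).
#'
#' @param table a [cell_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(inherits(table, "cell_table"))
  readr::write_csv(table$cells, path, progress = FALSE)
  invisible(path)
}

#' Cell density per imaged area or volume
#'
#' Number of cells of a phenotype divided by the imaged area (2D, cells/mm^2)
#' or volume (3D, cells/mm^3) — the per-sample density summaries used to
#' compare immune infiltration across tumors.
#'
#' @param table a [cell_table()] with `phenotype` assigned (see
#'   [apply_gates()]) and `imaged_volume` set.
#' @param phenotype phenotype label; a label absent from the table yields 0.
#' @param sample_id optional sample to restrict to; default pools all samples
#'   (imaged volumes are then summed).
#' @return density, a single number.
#' @export
cell_density <- function(table, phenotype, sample_id = NULL) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(table$imaged_volume)) {
    stop("imaged_volume is unset; supply it to cell_table()", call. = FALSE)
  }
  cells <- table$cells
  if (!"phenotype" %in% names(cells)) {
    stop("phenotype labels not assigned; run apply_gates() first",
         call. = FALSE)
  }
  vol <- table$imaged_volume
  if (!is.null(sample_id)) {
    cells <- cells[cells$sample_id %in% sample_id, , drop = FALSE]
    if (!is.null(names(vol))) vol <- vol[sample_id]
  }
  n <- sum(cells$phenotype == phenotype, na.rm = TRUE)
  n / sum(vol)
}

#' Construct a landmark set
#'
#' Typed anatomical anchors used in distance and region analyses: tumor-marker
#' spots (point objects marking cancer cells) and blood vessels, the latter as
#' point objects or centreline segments.
#'
#' @param kind one of `"cea_spot"`, `"vessel_point"`, `"vessel_segment"`.
#' @param points n x 2 matrix of (x, y) in um, for point kinds.
#' @param segments n x 4 matrix of (x1, y1, x2, y2) endpoint pairs in um, for
#'   `"vessel_segment"`; endpoints must be distinct.
#' @param sample_id sample the landmarks belong to.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(kind = c("cea_spot", "vessel_point",
                                  "vessel_segment"),
                         points = NULL, segments = NULL, sample_id = "sample") {
  kind <- match.arg(kind)
  if (kind == "vessel_segment") {
    stopifnot(!is.null(segments))
    segments <- as.matrix(segments)
    stopifnot(ncol(segments) == 4)
    degenerate <- segments[, 1] == segments[, 3] &
      segments[, 2] == segments[, 4]
    if (any(degenerate)) {
      stop("segment with coincident endpoints at row ", which(degenerate)[1],
           call. = FALSE)
    }
    colnames(segments) <- c("x1", "y1", "x2", "y2")
  } else {
    stopifnot(!is.null(points))
    points <- as.matrix(points)
    stopifnot(ncol(points) == 2)
    colnames(points) <- c("x", "y")
  }
  structure(list(kind = kind, points = points, segments = segments,
                 sample_id = sample_id),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  n <- if (x$kind == "vessel_segment") nrow(x$segments) else nrow(x$points)
  cat("<landmark_set> kind=", x$kind, ", ", n, " element(s), sample ",
      x$sample_id, "\n", sep = "")
  invisible(x)
}

#' Write / read landmark sets as CSV
#'
#' @param landmarks a [landmark_set()] or a list of them.
#' @param path CSV path.
#' @return `path` invisibly, or a list of `landmark_set` keyed by kind and
#'   sample for the reader.
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  rows <- lapply(landmarks, function(l) {
    if (l$kind == "vessel_segment") {
      tibble::tibble(sample_id = l$sample_id, kind = l$kind,
                     x = l$segments[, 1], y = l$segments[, 2],
                     x2 = l$segments[, 3], y2 = l$segments[, 4])
    } else {
      tibble::tibble(sample_id = l$sample_id, kind = l$kind,
                     x = l$points[, 1], y = l$points[, 2],
                     x2 = NA_real_, y2 = NA_real_)
    }
  })
  readr::write_csv(do.call(rbind, rows), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- list()
  for (sid in unique(raw$sample_id)) {
    for (k in unique(raw$kind[raw$sample_id == sid])) {
      sub <- raw[raw$sample_id == sid & raw$kind == k, , drop = FALSE]
      out[[paste(sid, k, sep = ".")]] <- if (k == "vessel_segment") {
        landmark_set(k, segments = as.matrix(sub[, c("x", "y", "x2", "y2")]),
                     sample_id = sid)
      } else {
        landmark_set(k, points = as.matrix(sub[, c("x", "y")]),
                     sample_id = sid)
      }
    }
  }
  out
}

#' Per-sample metadata with caliper measurements
#'
#' Holds treatment group and tumor caliper length/width (mm) at two
#' timepoints, from which volumes and the fold change in tumor volume are
#' derived (see [tumor_volume()]).
#'
#' @param sample_id character vector.
#' @param group treatment group per sample.
#' @param length_t0,width_t0,length_t1,width_t1 caliper measures, mm, with
#'   width <= length by convention.
#' @return tibble of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, group,
                            length_t0, width_t0, length_t1, width_t1) {
  stopifnot(all(length_t0 > 0), all(width_t0 > 0),
            all(length_t1 > 0), all(width_t1 > 0))
  if (any(width_t0 > length_t0) || any(width_t1 > length_t1)) {
    stop("width exceeds length; caliper convention is width <= length",
         call. = FALSE)
  }
  out <- tibble::tibble(sample_id = as.character(sample_id),
                        group = group,
                        length_t0 = length_t0, width_t0 = width_t0,
                        length_t1 = length_t1, width_t1 = width_t1)
  class(out) <- c("sample_metadata", class(out))
  out
}
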