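#' Caliper tumor volume
#'
#' The standard caliper estimate: half of length times width squared.
#'
#' @param length_mm,width_mm caliper measures, mm; must be positive.
#' @return volume, mm^3.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("caliper measures must be positive", call. = FALSE)
  }
  0.5 * length_mm * width_mm^2
}

#' Tumor-volume fold change
#'
#' Ratio of the caliper volume at the end timepoint to the volume at
#' initiation of therapy.
#'
#' @param metadata a [sample_metadata()] tibble.
#' @return tibble with `sample_id`, `v0`, `v1` (mm^3) and `fold_change`.
#' @export
volume_fold_change <- function(metadata) {
  v0 <- tumor_volume(metadata$length_t0, metadata$width_t0)
  v1 <- tumor_volume(metadata$length_t1, metadata$width_t1)
  tibble::tibble(sample_id = metadata$sample_id, v0 = v0, v1 = v1,
                 fold_change = v1 / v0)
}

#' Per-sample infiltrated-to-excluded region ratio
#'
#' The spatial biomarker: per sample, the summed prevalence of T-cell-rich
#' regions divided by the summed prevalence of tumor regions. Samples with
#' zero tumor-region prevalence get an infinite ratio and are flagged; a
#' log-ratio is reported alongside.
#'
#' @param summary a [region_summary()].
#' @param sample_id optional subset of samples.
#' @return tibble with `sample_id`, `sum_t` (T-cell-rich prevalence),
#'   `sum_tumor`, `ratio`, `log_ratio` and `flagged` (infinite ratio).
#' @export
region_ratio <- function(summary, sample_id = NULL) {
  stopifnot(inherits(summary, "region_summary"))
  cls <- summary$region_class
  if (!any(cls == "tumor")) {
    stop("no region classified as tumor in the cohort; ",
         "revisit tau_c or the feature set", call. = FALSE)
  }
  prev <- summary$prevalence
  if (!is.null(sample_id)) prev <- prev[sample_id, , drop = FALSE]
  sum_t <- rowSums(prev[, cls == "t_cell_rich", drop = FALSE])
  sum_tumor <- rowSums(prev[, cls == "tumor", drop = FALSE])
  sum_t <- unname(sum_t); sum_tumor <- unname(sum_tumor)
  ratio <- ifelse(sum_tumor > 0, sum_t / sum_tumor, Inf)
  tibble::tibble(sample_id = rownames(prev), sum_t = sum_t,
                 sum_tumor = sum_tumor, ratio = ratio,
                 log_ratio = log(ratio),
                 flagged = !is.finite(ratio))
}

#' Association of a spatial biomarker with outcome
#'
#' Pearson correlation between a biomarker (region ratio, T-cell-rich region
#' sum, CD8 density, ...) and an outcome (tumor-volume fold change), with a
#' two-sided p-value from the t transform of the correlation. Non-finite
#' biomarker values (flagged infinite ratios) are excluded; a constant
#' biomarker yields NA.
#'
#' @param biomarker,outcome numeric vectors of equal length (>= 3 usable
#'   pairs).
#' @return list with `r`, `p`, `n`.
#' @export
outcome_association <- function(biomarker, outcome) {
  stopifnot(length(biomarker) == length(outcome))
  ok <- is.finite(biomarker) & is.finite(outcome)
  if (sum(ok) < 3) stop("need >= 3 samples with finite values",
                        call. = FALSE)
  x <- biomarker[ok]; y <- outcome[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, sum(ok)), n = sum(ok))
}

#' Cohort biomarker report
#'
#' Joins the per-sample region ratio with the tumor-volume fold change and
#' computes the cohort-level association (on the ratio and on the
#' T-cell-rich prevalence sum).
#'
#' @param summary a [region_summary()] over the cohort.
#' @param metadata a [sample_metadata()] tibble.
#' @return list with `per_sample` (tibble) and `association` /
#'   `association_sum_t` (each `r`, `p`, `n`).
#' @export
biomarker_report <- function(summary, metadata) {
  ratios <- region_ratio(summary)
  fc <- volume_fold_change(metadata)
  per <- merge(ratios, fc, by = "sample_id", sort = TRUE)
  per <- tibble::as_tibble(per)
  list(per_sample = per,
       association = outcome_association(per$ratio, per$fold_change),
       association_sum_t = outcome_association(per$sum_t, per$fold_change))
}

#' Run the full synthetic-cohort pipeline
#'
#' Chains simulate -> gate -> raster neighborhoods -> region clustering ->
#' biomarker on a synthetic cohort, with all randomness controlled by the
#' cohort seed. Returns every intermediate product.
#'
#' @param spec a [cohort_spec()] (or a pre-generated cohort from
#'   [generate_cohort()]).
#' @param panel gating panel; default [default_panel()].
#' @param r,s window radius and raster spacing, um.
#' @param k number of regions.
#' @param grid_dim,epochs SOM settings (see [train_regions()]).
#' @return list with `cohort`, `tables` (gated), `nt` (with regions),
#'   `model`, `summary`, `report`.
#' @export
run_pipeline <- function(spec = cohort_spec(), panel = default_panel(),
                         r = 50, s = 50, k = 6, grid_dim = c(8, 8),
                         epochs = 30) {
  cohort <- if (inherits(spec, "cohort_spec")) generate_cohort(spec) else spec
  tables <- lapply(cohort$samples, function(sm) apply_gates(sm$table, panel))
  nts <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    nts[[i]] <- raster_neighborhoods(
      tables[[i]], landmarks = cohort$samples[[i]]$landmarks, r = r, s = s,
      phenotypes = panel_labels())
  }
  nt <- nts[[1]]
  nt$nb <- do.call(rbind, lapply(nts, `[[`, "nb"))
  model <- train_regions(nt, k = k, grid_dim = grid_dim, epochs = epochs,
                         seed = cohort$spec$seed)
  nt <- assign_regions(nt, model)
  summ <- region_summary(nt)
  report <- biomarker_report(summ, cohort$metadata)
  list(cohort = cohort, tables = tables, nt = nt, model = model,
       summary = summ, report = report)
}

#' Write the pipeline's outputs as CSV files
#'
#' Writes the gated cell tables, the neighborhood table with regions, the
#' region heatmap and prevalence matrices, and the per-sample biomarker
#' report into a directory. Deterministic inputs produce byte-identical
#' files.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- do.call(rbind, lapply(result$tables, function(t) t$cells))
  readr::write_csv(cells, file.path(dir, "cells_gated.csv"),
                   progress = FALSE)
  write_neighborhoods(result$nt, file.path(dir, "neighborhoods.csv"))
  heat <- tibble::as_tibble(as.data.frame(result$summary$heatmap))
  heat <- cbind(tibble::tibble(region = rownames(result$summary$heatmap)),
                heat)
  readr::write_csv(heat, file.path(dir, "region_heatmap.csv"),
                   progress = FALSE)
  prev <- tibble::as_tibble(as.data.frame(result$summary$prevalence))
  prev <- cbind(tibble::tibble(
    sample_id = rownames(result$summary$prevalence)), prev)
  readr::write_csv(prev, file.path(dir, "region_prevalence.csv"),
                   progress = FALSE)
  readr::write_csv(result$report$per_sample,
                   file.path(dir, "biomarker_report.csv"), progress = FALSE)
  invisible(dir)
}
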