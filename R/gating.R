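#' Hierarchical threshold gating
#'
#' Histocytometry classifies segmented cell objects into phenotypes by
#' flow-cytometry-style gating on per-channel MFIs. Here the interactive
#' gates are replaced by a tree of absolute per-channel threshold predicates:
#' each node carries a conjunction of comparisons (channel, op, cutoff);
#' children are evaluated, in document order, only on cells that pass the
#' parent; the first terminal node reached assigns its phenotype label; cells
#' that fall through every branch are labelled `"other"`.
#'
#' @name gating
NULL

gate_node <- function(name, when = list(), label = NULL, children = list()) {
  structure(list(name = name, when = when, label = label,
                 children = children), class = "gate_node")
}

#' Parse a gate tree configuration into a phenotype panel
#'
#' @param config a nested list (or path to a YAML file holding one) with
#'   elements `name`, optional `when` (list of `channel`, `op` in
#'   `>`, `<`, `>=`, `<=`, `cutoff`), optional `label` (terminal phenotype),
#'   and optional `children` (list of nodes). The root's `when` is ignored.
#' @return object of class `phenotype_panel` with elements `root`, `labels`
#'   and `channels`.
#' @seealso [default_panel()] for the shipped panel mirroring the myeloid and
#'   T-cell subsets analysed in the pipeline.
#' @export
parse_gate_tree <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  build <- function(node) {
    when <- lapply(node$when, function(w) {
      stopifnot(w$op %in% c(">", "<", ">=", "<="))
      list(channel = w$channel, op = w$op, cutoff = as.numeric(w$cutoff))
    })
    children <- lapply(node$children, build)
    gate_node(name = node$name %||% "node", when = when,
              label = node$label, children = children)
  }
  root <- build(config)
  labels <- collect_labels(root)
  if (anyDuplicated(labels)) {
    stop("duplicate terminal label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(root = root, labels = labels,
                 channels = collect_channels(root)),
            class = "phenotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collect_labels <- function(node) {
  c(if (!is.null(node$label)) node$label,
    unlist(lapply(node$children, collect_labels)))
}

collect_channels <- function(node) {
  unique(c(vapply(node$when, function(w) w$channel, character(1)),
           unlist(lapply(node$children, collect_channels))))
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat("<phenotype_panel> ", length(x$labels), " terminal labels, channels: ",
      paste(x$channels, collapse = ", "), "\n", sep = "")
  show <- function(node, depth) {
    pred <- if (length(node$when) > 0) {
      paste(vapply(node$when, function(w)
        paste0(w$channel, w$op, w$cutoff), character(1)), collapse = " & ")
    } else "(all)"
    cat(strrep("  ", depth), node$name, ": ", pred,
        if (!is.null(node$label)) paste0(" -> ", node$label), "\n", sep = "")
    for (ch in node$children) show(ch, depth + 1)
  }
  show(x$root, 0)
  invisible(x)
}

#' Default phenotype panel
#'
#' The shipped gate tree reproducing the subset hierarchy used throughout the
#' pipeline: CD3+CD8+ T cells stratified by TCF1/PD1 into resource
#' (TCF1+PD1+), effector (TCF1-PD1+) and other CD8 cells; CD3+CD8- putative
#' CD4 T cells; CD3- CD11c+MHCII+ dendritic cells split into CD103+ DC1 and
#' SIRPa+ DC2; CD11c- CD206+ macrophages; CD11c-CD206-SIRPa+ macrophages
#' split by MHCII. Thresholds are stand-ins calibrated to the synthetic
#' generator's bimodal intensity model, not published cutoffs (the original
#' gates were set interactively).
#'
#' @return a [parse_gate_tree()] panel with the 10 standard labels.
#' @export
default_panel <- function() {
  parse_gate_tree(system.file("extdata", "default_panel.yaml",
                              package = "tmemap", mustWork = TRUE))
}

#' Standard phenotype labels
#' @return character vector of the 10 labels of [default_panel()].
#' @export
panel_labels <- function() {
  c("DC1", "DC2", "CD206_Mf", "MHCII+_Mf", "MHCII-_Mf",
    "CD8_TCF1+PD1+", "CD8_TCF1-PD1+", "CD8_other", "CD4_T", "other")
}

eval_predicate <- function(cells, when) {
  pass <- rep(TRUE, nrow(cells))
  for (w in when) {
    if (!w$channel %in% names(cells)) {
      stop("gate references channel '", w$channel,
           "' absent from the cell table", call. = FALSE)
    }
    v <- cells[[w$channel]]
    pass <- pass & switch(w$op,
                          ">"  = v >  w$cutoff,
                          "<"  = v <  w$cutoff,
                          ">=" = v >= w$cutoff,
                          "<=" = v <= w$cutoff)
  }
  pass
}

#' Apply a phenotype panel to a cell table
#'
#' Deterministically assigns every cell exactly one phenotype label by
#' routing it down the gate tree (first matching child at each level);
#' unresolved cells get `"other"`.
#'
#' @param table a [cell_table()].
#' @param panel a [parse_gate_tree()] panel; default [default_panel()].
#' @return the `cell_table` with its `phenotype` column filled; per-label
#'   counts are attached as attribute `"gate_counts"`.
#' @export
apply_gates <- function(table, panel = default_panel()) {
  stopifnot(inherits(table, "cell_table"), inherits(panel, "phenotype_panel"))
  cells <- table$cells
  missing <- setdiff(panel$channels, names(cells))
  if (length(missing) > 0) {
    stop("cell table lacks channel(s) required by the panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- rep(NA_character_, nrow(cells))
  route <- function(node, idx) {
    if (length(idx) == 0) return()
    taken <- rep(FALSE, length(idx))
    for (child in node$children) {
      pass <- eval_predicate(cells[idx, , drop = FALSE], child$when)
      sel <- idx[pass & !taken]
      taken <- taken | pass
      if (length(sel) == 0) next
      if (!is.null(child$label)) {
        labels[sel] <<- child$label
      } else {
        route(child, sel)
      }
    }
  }
  route(panel$root, seq_len(nrow(cells)))
  labels[is.na(labels)] <- "other"
  table$cells$phenotype <- labels
  attr(table, "gate_counts") <- base::table(factor(labels,
    levels = union(panel$labels, "other")))
  table
}
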