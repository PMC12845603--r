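# Supervised-learning targets for stress and workload feature tables.

label_modes <- c("stress_binary_med_vs_cp", "stress_binary_eo_vs_cp",
                 "stress_3class", "stress_regression",
                 "workload_binary", "workload_3class")

#' Label specification
#'
#' @param mode One of `"stress_binary_med_vs_cp"` (meditation = low vs cold
#'   pressor = high), `"stress_binary_eo_vs_cp"`, `"stress_3class"`,
#'   `"stress_regression"` (target = the block's subjective rating, kept on
#'   the 1-9 scale), `"workload_binary"` (lowest vs highest difficulty;
#'   medium excluded), or `"workload_3class"`.
#' @return An object of class `label_spec`.
#' @export
label_spec <- function(mode) {
  mode <- match.arg(mode, label_modes)
  structure(list(mode = mode), class = "label_spec")
}

#' Assign supervised targets to a feature table
#'
#' Filters the table to the rows the labelling mode uses and attaches the
#' target: a `label` factor for classification modes, or a numeric `rating`
#' target for `stress_regression` (every segment of a block inherits the
#' block's single subjective rating).
#'
#' @param table A feature table with provenance columns (`condition` for
#'   stress modes, `level` for workload modes, `rating` for regression).
#' @param spec A [label_spec()] (or a mode string).
#' @return The labelled feature table.
#' @export
#' @examples
#' tbl <- tibble::tibble(condition = c("meditation", "cold_pressor"), x = 1:2)
#' assign_labels(tbl, "stress_binary_med_vs_cp")$label
assign_labels <- function(table, spec) {
  if (is.character(spec)) spec <- label_spec(spec)
  stopifnot(inherits(spec, "label_spec"))
  mode <- spec$mode
  if (grepl("^stress", mode) && !"condition" %in% names(table)) {
    abort("stress labelling needs a `condition` column.")
  }
  if (grepl("^workload", mode) && !"level" %in% names(table)) {
    abort("workload labelling needs a `level` column.")
  }
  cond <- function(x) as.character(x)
  switch(
    mode,
    stress_binary_med_vs_cp = {
      out <- table |> filter(cond(.data$condition) %in% c("meditation", "cold_pressor"))
      out$label <- factor(ifelse(cond(out$condition) == "meditation", "low", "high"),
                          levels = c("low", "high"))
      out
    },
    stress_binary_eo_vs_cp = {
      out <- table |> filter(cond(.data$condition) %in% c("eyes_open", "cold_pressor"))
      out$label <- factor(ifelse(cond(out$condition) == "eyes_open", "low", "high"),
                          levels = c("low", "high"))
      out
    },
    stress_3class = {
      out <- table |>
        filter(cond(.data$condition) %in% c("meditation", "eyes_open", "cold_pressor"))
      out$label <- factor(cond(out$condition),
                          levels = c("meditation", "eyes_open", "cold_pressor"))
      out
    },
    stress_regression = {
      if (!"rating" %in% names(table)) {
        abort("regression labelling needs a `rating` column (one per block).")
      }
      if (anyNA(table$rating)) abort("missing rating for at least one block.")
      table
    },
    workload_binary = {
      out <- table |> filter(cond(.data$level) %in% c("low", "high"))
      out$label <- factor(cond(out$level), levels = c("low", "high"))
      out
    },
    workload_3class = {
      out <- table |> filter(cond(.data$level) %in% c("low", "medium", "high"))
      out$label <- factor(cond(out$level), levels = c("low", "medium", "high"))
      out
    }
  )
}
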