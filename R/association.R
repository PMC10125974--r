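# Random-forest ranking of physiological activities against the imaging
# parameters, and group-wise distribution comparisons.

#' Encode harmonised activity labels as a numeric feature matrix
#'
#' Default ordinal coding `active = 1`, `inconclusive = 0.5`,
#' `inactive = 0`; `missing` cells are imputed with the column median so no
#' chemical is dropped.  One-hot coding (one indicator column per observed
#' label) is available as an alternative.
#'
#' @param matrix Long label tibble from [build_activity_matrix()] (or any
#'   tibble with `chemical_id`, `activity`, `label`).
#' @param coding `"ordinal"` (default) or `"onehot"`.
#' @return Tibble with `chemical_id` and one numeric column per activity
#'   (or per activity x label under one-hot coding).
#' @export
#' @examples
#' m <- tibble::tibble(chemical_id = c("a", "b", "c"),
#'                     activity = "x",
#'                     label = c("active", "inactive", "missing"))
#' encode_activities(m)
encode_activities <- function(matrix, coding = c("ordinal", "onehot")) {
  coding <- match.arg(coding)
  tbl <- tibble::as_tibble(matrix)
  check_vocab(tbl$label, c("active", "inconclusive", "inactive", "missing"),
              "activity label")
  if (coding == "ordinal") {
    scores <- c(active = 1, inconclusive = 0.5, inactive = 0)
    wide <- tbl |>
      dplyr::mutate(score = unname(scores[.data$label])) |>
      dplyr::select("chemical_id", "activity", "score") |>
      tidyr::pivot_wider(names_from = "activity", values_from = "score")
    # median imputation per activity column
    wide |>
      dplyr::mutate(dplyr::across(
        -"chemical_id",
        function(v) {
          if (all(is.na(v))) {
            stop_input("an activity column is missing for every chemical")
          }
          dplyr::if_else(is.na(v), stats::median(v, na.rm = TRUE), v)
        }
      ))
  } else {
    tbl |>
      dplyr::filter(.data$label != "missing") |>
      dplyr::mutate(col = paste(.data$activity, .data$label, sep = "="),
                    one = 1) |>
      dplyr::select("chemical_id", "col", "one") |>
      tidyr::pivot_wider(names_from = "col", values_from = "one",
                         values_fill = 0)
  }
}

#' Decode a one-hot activity encoding back to labels
#'
#' @param onehot Wide tibble from `encode_activities(..., "onehot")`.
#' @return Long tibble with `chemical_id`, `activity`, `label`.
#' @export
decode_onehot <- function(onehot) {
  onehot |>
    tidyr::pivot_longer(-"chemical_id", names_to = "col", values_to = "one") |>
    dplyr::filter(.data$one == 1) |>
    tidyr::separate_wider_delim("col", "=", names = c("activity", "label")) |>
    dplyr::select("chemical_id", "activity", "label")
}

#' Rank activities by random-forest importance for one imaging parameter
#'
#' Fits a regression random forest of the continuous parameter ratio on the
#' encoded activity features and ranks features by total node-impurity
#' (residual sum of squares) decrease -- the "increase in node purity"
#' importance.  Ties are broken alphabetically by activity name so the
#' ranking is deterministic given the seed.
#'
#' @param features Tibble from [encode_activities()] (`chemical_id` +
#'   numeric activity columns).
#' @param response Tibble with `chemical_id` and the response column.
#' @param response_col Name of the response column in `response`.
#' @param n_trees Number of trees (>= 100).
#' @param seed Integer seed for the forest's bootstrap/feature sampling.
#' @param top_n Rows reported by [head()]-style helpers downstream
#'   (stored as an attribute; all features are returned).
#' @return Object of class `igem_importance`: tibble `activity`,
#'   `importance`, `rank`, with the fitted forest in attribute `forest`.
#' @export
rf_importance <- function(features, response, response_col, n_trees = 500,
                          seed = 0, top_n = 30) {
  if (n_trees < 100) stop_input("`n_trees` must be at least 100")
  joined <- dplyr::inner_join(features, response, by = "chemical_id")
  if (nrow(joined) < 10) stop_input("need at least 10 chemicals")
  y <- joined[[response_col]]
  if (is.null(y)) stop_input(paste0("response column '", response_col,
                                    "' not found"))
  if (!all(is.finite(y))) stop_input("response must be finite")
  if (stats::var(y) == 0) stop_input("constant response; importance undefined")
  feat_names <- sort(setdiff(names(features), "chemical_id"))
  # canonical column order makes the ranking invariant to how the caller
  # ordered the feature columns
  x <- as.data.frame(joined[feat_names])
  names(x) <- make.names(names(x))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    fit <- randomForest::randomForest(
      x = x, y = y, ntree = n_trees,
      mtry = max(1, ceiling(ncol(x) / 3)),
      importance = FALSE
    )
  })
  imp <- fit$importance[, "IncNodePurity"]
  out <- tibble::tibble(
    activity = feat_names,
    importance = unname(imp)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$activity) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(out, forest = fit, top_n = top_n, response = response_col,
            class = c("igem_importance", class(out)))
}

#' Compare an imaging parameter's distribution across activity labels
#'
#' Kruskal-Wallis omnibus across the `active` / `inconclusive` / `inactive`
#' groups, with Steel-Dwass pairwise comparisons.
#'
#' @param ratios Tibble with `chemical_id` and the parameter column.
#' @param labels Tibble with `chemical_id`, `label` for one activity;
#'   `missing` rows are dropped.
#' @param parameter Name of the parameter column in `ratios`.
#' @return As [kw_steel_dwass()].
#' @export
compare_by_label <- function(ratios, labels, parameter) {
  joined <- dplyr::inner_join(ratios, labels, by = "chemical_id") |>
    dplyr::filter(.data$label != "missing")
  kw_steel_dwass(joined[[parameter]], joined$label)
}
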