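# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a chemical clustering
#'
#' @param x An `igem_clustering`.
#' @param ... Unused.
#' @return Tibble with one row per chemical: `chemical_id`, `cluster_id`.
#' @method tidy igem_clustering
#' @export
tidy.igem_clustering <- function(x, ...) {
  x$clusters
}

#' One-row clustering summary
#'
#' @param x An `igem_clustering`.
#' @param ... Unused.
#' @return Tibble with `n_chemicals`, `k`, `merge_height_max`.
#' @method glance igem_clustering
#' @export
glance.igem_clustering <- function(x, ...) {
  tibble::tibble(n_chemicals = nrow(x$clusters), k = x$k,
                 merge_height_max = max(x$hclust$height))
}

#' Tidy an importance ranking
#'
#' @param x An `igem_importance`.
#' @param ... Unused.
#' @return Tibble with `activity`, `importance`, `rank`.
#' @method tidy igem_importance
#' @export
tidy.igem_importance <- function(x, ...) {
  tibble::as_tibble(x)[c("activity", "importance", "rank")]
}

#' One-row importance-ranking summary
#'
#' @param x An `igem_importance`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `response`, `top_activity`.
#' @method glance igem_importance
#' @export
glance.igem_importance <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 response = attr(x, "response"),
                 top_activity = x$activity[x$rank == 1])
}

#' Tidy Steel-Dwass pairwise results
#'
#' @param x An `igem_steel_dwass`.
#' @param ... Unused.
#' @return Tibble with `group1`, `group2`, `statistic`, `p_value`.
#' @method tidy igem_steel_dwass
#' @export
tidy.igem_steel_dwass <- function(x, ...) {
  tibble::as_tibble(x)
}
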