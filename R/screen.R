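# Normalisation to vehicle control, viability gating, correlation
# clustering and A/B/C category calling for the chemical screen.

ratio_params <- c("foci_intensity", "foci_area", "foci_count", "nuclei")
well_param_cols <- c(
  foci_intensity = "foci_intensity_per_nucleus",
  foci_area = "foci_area_per_nucleus",
  foci_count = "foci_count_per_nucleus",
  nuclei = "nuclei_count"
)

#' Ratio of treated to vehicle-control well measures
#'
#' For each of the four parameters the ratio of the treated replicate mean
#' to the control replicate mean, with a delta-method standard error
#' propagated from the replicate variation of both arms.
#'
#' @param treated,control Tibbles of replicate well measures (rows =
#'   replicate wells) as returned by [measure_well()].
#' @return Tibble with `parameter`, `ratio`, `se`.
#' @export
#' @examples
#' t <- tibble::tibble(nuclei_count = c(90, 100, 110),
#'                     foci_intensity_per_nucleus = c(90, 100, 110),
#'                     foci_area_per_nucleus = c(8, 8, 8),
#'                     foci_count_per_nucleus = c(2, 2, 2))
#' ratio_to_control(t, dplyr::mutate(t, foci_intensity_per_nucleus =
#'                                        c(200, 200, 200)))
ratio_to_control <- function(treated, control) {
  if (nrow(treated) < 1 || nrow(control) < 1) {
    stop_input("need at least one replicate in each arm")
  }
  one <- function(par) {
    col <- well_param_cols[[par]]
    x <- treated[[col]]; y <- control[[col]]
    if (is.null(x) || is.null(y)) {
      stop_input(paste0("column '", col, "' missing from the well measures"))
    }
    if (anyNA(y) || mean(y) <= 0) {
      stop_input(paste0("control parameter '", par,
                        "' is zero or undefined; cannot form a ratio"))
    }
    mx <- mean(x); my <- mean(y)
    se_x <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    se_y <- if (length(y) > 1) stats::sd(y) / sqrt(length(y)) else 0
    r <- mx / my
    tibble::tibble(parameter = par, ratio = r,
                   se = abs(r) * sqrt((se_x / mx)^2 + (se_y / my)^2))
  }
  purrr::map(ratio_params, one) |> purrr::list_rbind()
}

#' Flag chemicals failing the viability gate
#'
#' Wells whose nuclei ratio falls below `min_fraction` of the vehicle
#' control indicate cytotoxicity rather than an epigenetic read-out; they
#' are flagged (and excluded from clustering by default) but retained in
#' the output.  The boundary is inclusive: a nuclei ratio exactly at
#' `min_fraction` passes.
#'
#' @param table Screen ratio tibble with a `nuclei` column.
#' @param min_fraction Minimum tolerated nuclei ratio (default 0.7).
#' @return The input with a logical `viable` column added.
#' @export
viability_gate <- function(table, min_fraction = 0.7) {
  if (!"nuclei" %in% names(table)) stop_input("`table` must have a `nuclei` column")
  dplyr::mutate(table, viable = .data$nuclei >= min_fraction)
}

#' Cluster chemicals by their four-parameter ratio profiles
#'
#' Agglomerative clustering with distance 1 - Pearson correlation between
#' chemicals' (foci intensity, foci area, foci count, nuclei) ratio
#' profiles and average linkage, cut into `k` clusters.
#'
#' @param table Screen ratio tibble (`chemical_id` + the four ratio
#'   columns). Rows flagged `viable = FALSE` are dropped first.
#' @param k Number of clusters to cut (default 3).
#' @return Object of class `igem_clustering`: list with `clusters` (tibble:
#'   `chemical_id`, `cluster_id`), `hclust`, and the profile `table` used.
#' @export
cluster_chemicals <- function(table, k = 3) {
  if ("viable" %in% names(table)) {
    table <- dplyr::filter(table, .data$viable)
  }
  miss <- setdiff(c("chemical_id", ratio_params), names(table))
  if (length(miss)) {
    stop_input(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(table[ratio_params])
  if (anyNA(x)) stop_input("ratio table contains missing values")
  if (nrow(x) < k) stop_input("need at least `k` chemicals to cut k clusters")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop_input(paste0("constant ratio profile (Pearson distance undefined) for: ",
                      paste(table$chemical_id[sds == 0], collapse = ", ")))
  }
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = "average")
  hc$labels <- table$chemical_id
  cl <- stats::cutree(hc, k = k)
  structure(
    list(
      clusters = tibble::tibble(chemical_id = table$chemical_id,
                                cluster_id = unname(cl)),
      hclust = hc,
      table = tibble::as_tibble(table),
      k = k
    ),
    class = "igem_clustering"
  )
}

#' @export
print.igem_clustering <- function(x, ...) {
  cat("<igem_clustering>", nrow(x$clusters), "chemicals in", x$k, "clusters\n")
  print(dplyr::count(x$clusters, .data$cluster_id))
  invisible(x)
}

#' Export a clustering dendrogram as Newick text
#'
#' @param clustering An `igem_clustering`.
#' @param path Optional file to write; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
cluster_newick <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "igem_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Assign methylation categories A/B/C to clusters
#'
#' Per cluster, the mean of the three foci-parameter ratios `m` determines
#' the label: hypermethylation-like (B) when `m > 1 + delta`,
#' hypomethylation-like (A) when `m < 1 - delta`, else intermediate (C).
#' With exactly three clusters the labels are forced distinct by ranking
#' cluster means (lowest mean is A, highest B, middle C), which also
#' resolves clusters sitting inside the +-delta band.
#'
#' @param clustering An `igem_clustering` from [cluster_chemicals()].
#' @param delta Half-width of the "little or no effect" band (default 0.05).
#' @return Tibble with `chemical_id`, `cluster_id`, `category`.
#' @export
assign_categories <- function(clustering, delta = 0.05) {
  stopifnot(inherits(clustering, "igem_clustering"))
  tab <- dplyr::left_join(clustering$clusters, clustering$table,
                          by = "chemical_id")
  means <- tab |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      m = mean(c(.data$foci_intensity, .data$foci_area, .data$foci_count)),
      .groups = "drop"
    )
  if (clustering$k == 3 && nrow(means) == 3) {
    ord <- order(means$m)
    means$category <- NA_character_
    means$category[ord] <- c("A", "C", "B")
  } else {
    means$category <- dplyr::case_when(
      means$m > 1 + delta ~ "B",
      means$m < 1 - delta ~ "A",
      TRUE ~ "C"
    )
  }
  dplyr::left_join(clustering$clusters,
                   dplyr::select(means, "cluster_id", "category"),
                   by = "cluster_id")
}

#' One-way ANOVA with Tukey multiple comparisons across dose groups
#'
#' Omnibus F-test across all groups followed by Tukey honest significant
#' difference p-values for every pairwise comparison, as used for
#' concentration-response read-outs of the imaging parameters.
#'
#' @param values Numeric response vector.
#' @param group Factor/character of the same length (dose or condition).
#' @return List with `anova` (tibble: statistic, p_value) and `pairwise`
#'   (tibble: comparison, estimate, p_value).
#' @export
dose_response_test <- function(values, group) {
  if (length(values) != length(group)) stop_input("lengths differ")
  group <- factor(group)
  if (nlevels(group) < 2) stop_input("need at least two groups")
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(
    anova = tibble::tibble(statistic = an$`F value`[1],
                           p_value = an$`Pr(>F)`[1]),
    pairwise = tibble::tibble(comparison = rownames(tk),
                              estimate = tk[, "diff"],
                              p_value = tk[, "p adj"])
  )
}
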