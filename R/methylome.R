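# Array beta-value differential analytics: log2 summaries, DiffScore
# calls, genome-context distributions, gene panels and the
# methylation-expression funnel.

#' Per-site log2 beta ratios and genome-wide mean
#'
#' Beta values are floored at `eps` before the ratio so unmethylated sites
#' do not produce infinite ratios.
#'
#' @param beta_treated,beta_control Numeric beta vectors over matched
#'   probes.
#' @param eps Floor applied to both arguments (default 1e-3).
#' @return List with `log2_ratio` (per site) and `mean` (genome-wide mean).
#' @export
beta_log2_summary <- function(beta_treated, beta_control, eps = 1e-3) {
  if (length(beta_treated) != length(beta_control)) {
    stop_input("treated and control beta vectors must be matched")
  }
  lr <- log2(pmax(beta_treated, eps) / pmax(beta_control, eps))
  list(log2_ratio = lr, mean = mean(lr))
}

#' Signed differential methylation score (DiffScore)
#'
#' `score = sign(beta_t - beta_c) * (-10 log10 p)`; sites whose score is
#' strictly above the threshold -- the score at p = 0.05, which prints as
#' 13 -- are called hypermethylated, so a site at exactly p = 0.05
#' (score 13.0103) is not called.  With single arrays per
#' condition the p-value comes from a Gaussian measurement-noise model of
#' beta with per-array noise `sigma_beta`:
#' `p = 2 * pnorm(-|db| / (sqrt(2) * sigma_beta))`.
#'
#' @param beta_treated,beta_control Matched beta vectors.
#' @param p Optional per-site p-values; when `NULL` they are computed from
#'   the noise model.
#' @param sigma_beta Per-array beta measurement noise sd (default 0.03).
#' @param threshold Call threshold on the score (strict `>`; default
#'   `-10*log10(0.05)`, i.e. the score at p = 0.05).
#' @return Tibble with `delta_beta`, `p_value`, `diff_score`,
#'   `hypermethylated`.
#' @export
#' @examples
#' diff_score(0.8, 0.4, p = 0.01)   # score 20
diff_score <- function(beta_treated, beta_control, p = NULL,
                       sigma_beta = 0.03, threshold = -10 * log10(0.05)) {
  if (length(beta_treated) != length(beta_control)) {
    stop_input("treated and control beta vectors must be matched")
  }
  db <- beta_treated - beta_control
  if (is.null(p)) {
    p <- 2 * stats::pnorm(-abs(db) / (sqrt(2) * sigma_beta))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_input("p-values must be in [0,1]")
  score <- sign(db) * (-10 * log10(pmax(p, 1e-300)))
  score[db == 0] <- 0
  tibble::tibble(
    delta_beta = db,
    p_value = p,
    diff_score = score,
    hypermethylated = score > threshold
  )
}

#' Genome-context distribution of called differential sites
#'
#' @param sites Tibble with `probe_id` for the called sites.
#' @param annotation Probe annotation tibble (`probe_id`, `refgene_group`,
#'   `cpg_context`).
#' @return List of two tibbles, `refgene_group` and `cpg_context`, each
#'   with `count` and `proportion` (proportions sum to 1 per axis); both
#'   empty with a warning attribute when no sites are called.
#' @export
region_distribution <- function(sites, annotation) {
  ann <- dplyr::inner_join(tibble::as_tibble(sites)["probe_id"],
                           annotation, by = "probe_id")
  one_axis <- function(col) {
    if (nrow(ann) == 0) {
      return(tibble::tibble(!!col := character(0), count = integer(0),
                            proportion = numeric(0)))
    }
    ann |>
      dplyr::count(.data[[col]], name = "count") |>
      dplyr::mutate(proportion = .data$count / sum(.data$count))
  }
  out <- list(refgene_group = one_axis("refgene_group"),
              cpg_context = one_axis("cpg_context"))
  attr(out, "empty") <- nrow(ann) == 0
  out
}

#' Per-gene promoter methylation summary over a gene panel
#'
#' Sites are assigned to a gene when its symbol matches the probe's gene
#' annotation.  For each panel gene two change summaries are reported: the
#' per-site mean of log2 beta ratios (`mean_log2_ratio`) and the log2
#' ratio of the gene's mean methylation rates (`log2_rate_ratio`).  The
#' rate ratio is the robust funnel measure: averaging betas before the
#' ratio avoids the heavy-tailed noise of log ratios at nearly
#' unmethylated probes.
#'
#' @param beta Beta tibble (`probe_id` + sample columns).
#' @param annotation Probe annotation (`probe_id`, `gene`).
#' @param genes Character vector of gene symbols to summarise.
#' @param treated,control Sample column names in `beta`.
#' @param eps Beta floor for the log2 ratio.
#' @return Tibble with `gene`, `n_sites`, `mean_log2_ratio`,
#'   `log2_rate_ratio` (both NA when a gene has no probes).
#' @export
gene_panel_methylation <- function(beta, annotation, genes, treated, control,
                                   eps = 1e-3) {
  joined <- dplyr::inner_join(beta, annotation["probe_id"] |>
                                dplyr::bind_cols(gene = annotation$gene),
                              by = "probe_id") |>
    dplyr::filter(.data$gene %in% genes)
  lr <- beta_log2_summary(joined[[treated]], joined[[control]], eps)$log2_ratio
  summ <- tibble::tibble(gene = joined$gene, lr = lr,
                         bt = joined[[treated]], bc = joined[[control]]) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      mean_log2_ratio = mean(.data$lr),
      log2_rate_ratio = log2(pmax(mean(.data$bt), eps) /
                               pmax(mean(.data$bc), eps)),
      .groups = "drop")
  tibble::tibble(gene = genes) |>
    dplyr::left_join(summ, by = "gene") |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
}

#' Genes hypermethylated in common between two treatments
#'
#' A gene qualifies under one treatment when it has at least one called
#' hypermethylated site whose fold-change measure (beta ratio by default)
#' strictly exceeds `fold_threshold`; the intersection over both
#' treatments is returned.
#'
#' @param calls_a,calls_b Tibbles with `gene` and `fold_change` for the
#'   called sites of each treatment.
#' @param fold_threshold Strict lower bound on the fold change (default 10).
#' @return Sorted character vector of common gene symbols.
#' @export
common_hyper_genes <- function(calls_a, calls_b, fold_threshold = 10) {
  pick <- function(calls) {
    unique(calls$gene[calls$fold_change > fold_threshold & calls$gene != ""])
  }
  sort(intersect(pick(calls_a), pick(calls_b)))
}

#' Down-regulated / hypermethylated gene funnel
#'
#' Restricted to the commonly down-regulated gene set, counts how many
#' genes show a mean promoter methylation-rate gain (log2 rate ratio >
#' `min_effect`; falls back to the per-site mean log2 ratio when the rate
#' column is absent) under either treatment and under both.
#'
#' @param common_down Character vector of commonly down-regulated genes.
#' @param panel_meth_a,panel_meth_b Tibbles from
#'   [gene_panel_methylation()] for the two treatments.
#' @param min_effect Minimum log2 gain counted as an increase
#'   (default 0.1; see the methods vignette).
#' @return List with counts `n_down`, `n_meth_either`, `n_meth_both` and
#'   the corresponding gene vectors `meth_either`, `meth_both`.
#' @export
methylation_expression_funnel <- function(common_down, panel_meth_a,
                                          panel_meth_b, min_effect = 0.1) {
  if (length(common_down) == 0) {
    return(list(n_down = 0L, n_meth_either = 0L, n_meth_both = 0L,
                meth_either = character(0), meth_both = character(0)))
  }
  up_in <- function(pm) {
    m <- pm$log2_rate_ratio %||% pm$mean_log2_ratio
    pm$gene[!is.na(m) & m > min_effect]
  }
  a <- intersect(up_in(panel_meth_a), common_down)
  b <- intersect(up_in(panel_meth_b), common_down)
  either <- sort(union(a, b)); both <- sort(intersect(a, b))
  list(n_down = length(common_down),
       n_meth_either = length(either),
       n_meth_both = length(both),
       meth_either = either,
       meth_both = both)
}
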