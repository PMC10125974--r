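# RRBS call-table operations: coverage filtering, median normalisation,
# fixed-width tiling and per-gene summaries.

check_calls <- function(calls) {
  need <- c("chrom", "pos", "strand", "coverage", "n_meth")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop_input(paste("call table missing columns:",
                     paste(miss, collapse = ", ")))
  }
  if (any(calls$n_meth > calls$coverage)) {
    stop_input("n_meth exceeds coverage at some sites")
  }
  invisible(calls)
}

#' Coverage-filter an RRBS call table
#'
#' Removes bases with coverage strictly below `min_coverage` (default 10)
#' and bases above the per-sample `percentile` of coverage (default
#' 99.9th; likely PCR artifacts).  Sites between the two bounds, inclusive,
#' are always retained.
#'
#' @param calls Call tibble (`chrom`, `pos`, `strand`, `coverage`,
#'   `n_meth`).
#' @param min_coverage Minimum retained coverage (inclusive).
#' @param percentile Upper coverage quantile (in (0,1]); sites with
#'   coverage strictly above it are removed.
#' @return Filtered tibble; attribute `removed` records counts removed by
#'   each rule.
#' @export
rrbs_filter <- function(calls, min_coverage = 10, percentile = 0.999) {
  check_calls(calls)
  hi <- stats::quantile(calls$coverage, percentile, names = FALSE, type = 7)
  low <- calls$coverage < min_coverage
  high <- calls$coverage > hi
  out <- calls[!(low | high), , drop = FALSE]
  attr(out, "removed") <- c(low_coverage = sum(low),
                            high_coverage = sum(high & !low))
  out
}

#' Median-normalise coverage across RRBS samples
#'
#' Each sample's coverage is scaled by (median of the per-sample median
#' coverages) / (this sample's median coverage); methylated counts are
#' recomputed from the site's methylation fraction on the new coverage and
#' rounded, so each fraction moves by at most 0.5 / new coverage.
#'
#' @param samples Named list of call tibbles.
#' @return Named list of normalised call tibbles; attribute `factors`
#'   holds the per-sample scale factors.
#' @export
rrbs_normalize_coverage <- function(samples) {
  lapply(samples, check_calls)
  med <- vapply(samples, function(s) stats::median(s$coverage), numeric(1))
  target <- stats::median(med)
  fac <- target / med
  out <- purrr::imap(samples, function(s, nm) {
    f <- fac[[nm]]
    new_cov <- as.integer(round(s$coverage * f))
    frac <- ifelse(s$coverage > 0, s$n_meth / s$coverage, 0)
    dplyr::mutate(s,
                  n_meth = pmin(as.integer(round(frac * new_cov)), new_cov),
                  coverage = new_cov)
  })
  attr(out, "factors") <- fac
  out
}

#' Tile RRBS calls into fixed non-overlapping windows
#'
#' Counts are summed per `window`-base non-overlapping window across the
#' genome (windows start at 1, 1+window, ...; strands are merged --
#' non-directional protocol).
#'
#' @param calls Call tibble.
#' @param window Window width in bases (default 1000).
#' @return Tibble with `chrom`, `start` (1-based), `end`, `coverage`,
#'   `n_meth`, `fraction`.
#' @export
#' @examples
#' calls <- tibble::tibble(chrom = "chr1", pos = 1500, strand = "+",
#'                         coverage = 20L, n_meth = 15L)
#' rrbs_tile(calls)   # window [1001, 2000], fraction 0.75
rrbs_tile <- function(calls, window = 1000) {
  check_calls(calls)
  if (nrow(calls) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), coverage = integer(0),
                          n_meth = integer(0), fraction = numeric(0)))
  }
  calls |>
    dplyr::mutate(start = as.integer((.data$pos - 1) %/% window) * window + 1L) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(coverage = sum(.data$coverage),
                     n_meth = sum(.data$n_meth), .groups = "drop") |>
    dplyr::mutate(end = .data$start + as.integer(window) - 1L,
                  fraction = .data$n_meth / .data$coverage) |>
    dplyr::select("chrom", "start", "end", "coverage", "n_meth", "fraction") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Per-gene RRBS methylation change versus control
#'
#' Sites falling inside each gene's interval are summarised two ways:
#' the per-site mean of log2 fraction ratios (`mean_log2_ratio`) and the
#' log2 ratio of pooled methylation rates, sum(methylated)/sum(coverage)
#' treated vs control (`log2_rate_ratio`) -- the robust gene-level
#' measure (fractions floored at `eps`).
#'
#' @param calls_treated,calls_control Filtered call tibbles.
#' @param gene_map Tibble with `gene`, `chrom`, `start`, `end`.
#' @param eps Fraction floor for the log2 ratio.
#' @return Tibble with `gene`, `n_sites`, `mean_log2_ratio`,
#'   `log2_rate_ratio`.
#' @export
rrbs_gene_methylation <- function(calls_treated, calls_control, gene_map,
                                  eps = 1e-3) {
  check_calls(calls_treated); check_calls(calls_control)
  one_gene <- function(g, chrom, start, end) {
    pick <- function(calls) {
      dplyr::filter(calls, .data$chrom == !!chrom, .data$pos >= start,
                    .data$pos <= end)
    }
    t <- pick(calls_treated); c0 <- pick(calls_control)
    # per-site log2 ratios over positions present in both samples
    m <- dplyr::inner_join(t, c0, by = c("chrom", "pos", "strand"),
                           suffix = c("_t", "_c"))
    if (nrow(m) == 0) {
      return(tibble::tibble(gene = g, n_sites = 0L,
                            mean_log2_ratio = NA_real_,
                            log2_rate_ratio = NA_real_))
    }
    ft <- pmax(m$n_meth_t / m$coverage_t, eps)
    fc <- pmax(m$n_meth_c / m$coverage_c, eps)
    tibble::tibble(
      gene = g, n_sites = nrow(m),
      mean_log2_ratio = mean(log2(ft / fc)),
      log2_rate_ratio = log2(pmax(sum(m$n_meth_t) / sum(m$coverage_t), eps) /
                               pmax(sum(m$n_meth_c) / sum(m$coverage_c), eps)))
  }
  purrr::pmap(gene_map[c("gene", "chrom", "start", "end")],
              function(gene, chrom, start, end)
                one_gene(gene, chrom, start, end)) |>
    purrr::list_rbind()
}

#' Genome-wide RRBS methylation summary versus control
#'
#' Mean per-site log2 ratio of methylation fractions over sites present in
#' both samples.
#'
#' @param calls_treated,calls_control Filtered call tibbles.
#' @param eps Fraction floor.
#' @return One-row tibble with `n_sites` and `mean_log2_ratio`.
#' @export
rrbs_global_summary <- function(calls_treated, calls_control, eps = 1e-3) {
  m <- dplyr::inner_join(calls_treated, calls_control,
                         by = c("chrom", "pos", "strand"),
                         suffix = c("_t", "_c"))
  ft <- pmax(m$n_meth_t / m$coverage_t, eps)
  fc <- pmax(m$n_meth_c / m$coverage_c, eps)
  tibble::tibble(n_sites = nrow(m), mean_log2_ratio = mean(log2(ft / fc)))
}
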