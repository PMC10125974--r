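#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups the two samples are re-ranked jointly, the
#' rank-sum statistic is standardised with the tie-corrected variance
#' \deqn{V = \frac{n_i n_j}{N(N-1)} \sum_{l=1}^{N} \left(R_l -
#' \frac{N+1}{2}\right)^2,\qquad N = n_i + n_j,}
#' and \eqn{\sqrt{2}\,|t|} is referred to the studentized range
#' distribution with `k` groups and infinite degrees of freedom, giving a
#' two-sided p-value that is simultaneously adjusted over all pairs.  With
#' two groups this reduces to the tie-corrected normal-approximation
#' Wilcoxon rank-sum test.
#'
#' @param values Numeric response vector.
#' @param group Factor/character group labels (>= 2 groups, each n >= 2).
#' @return Object of class `igem_steel_dwass`: tibble with `group1`,
#'   `group2`, `statistic` (standardised rank statistic `t`) and `p_value`.
#' @export
#' @examples
#' steel_dwass(c(1:8, 11:18, 21:28), rep(c("a", "b", "c"), each = 8))
steel_dwass <- function(values, group) {
  if (length(values) != length(group)) stop_input("lengths differ")
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop_input("need at least two groups")
  ns <- table(group)
  if (any(ns < 2)) {
    stop_input(paste0("every group needs n >= 2; too small: ",
                      paste(names(ns)[ns < 2], collapse = ", ")))
  }
  pairs <- utils::combn(levels(group), 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- values[group == g1]; y <- values[group == g2]
    t_stat <- steel_dwass_stat(x, y)
    p <- stats::ptukey(sqrt(2) * abs(t_stat), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, statistic = t_stat,
                   p_value = p)
  }) |> purrr::list_rbind()
  structure(res, class = c("igem_steel_dwass", class(res)))
}

# standardised pairwise rank-sum statistic with tie correction
steel_dwass_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  v <- n1 * n2 / (n * (n - 1)) * sum((r - (n + 1) / 2)^2)
  if (v == 0) return(0)
  (w - e) / sqrt(v)
}

#' Kruskal-Wallis omnibus test plus Steel-Dwass pairwise comparisons
#'
#' @param values Numeric response vector.
#' @param group Group labels.
#' @return List with `omnibus` (tibble: statistic, p_value) and `pairwise`
#'   (an `igem_steel_dwass` tibble).
#' @export
kw_steel_dwass <- function(values, group) {
  kw <- stats::kruskal.test(values, factor(group))
  list(
    omnibus = tibble::tibble(statistic = unname(kw$statistic),
                             p_value = kw$p.value),
    pairwise = steel_dwass(values, group)
  )
}
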