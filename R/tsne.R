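#' t-SNE embedding of samples from fold-change profiles
#'
#' Exact (non-Barnes-Hut) t-SNE suitable for the handful of samples this
#' pipeline embeds: Gaussian input affinities calibrated to `perplexity`
#' by bisection, symmetrised, and a momentum gradient descent on the
#' Kullback-Leibler divergence to the Student-t output affinities.
#' Initialisation is the (deterministic) PCA projection plus a small
#' seeded jitter, so coordinates are reproducible given the seed.
#'
#' @param x Numeric matrix (samples in rows) or a tibble whose first
#'   column is an identifier followed by numeric feature columns.
#' @param seed Integer seed for the jitter.
#' @param perplexity Target perplexity; capped at `(n - 1) / 3` and
#'   defaulting to `min(5, (n - 1) / 3)` for the small panels used here.
#' @param n_iter Gradient-descent iterations.
#' @return Tibble with `sample`, `tsne1`, `tsne2`.
#' @export
tsne_embed <- function(x, seed = 0, perplexity = NULL, n_iter = 500) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    x <- as.matrix(x[-1])
  } else {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    x <- as.matrix(x)
  }
  n <- nrow(x)
  if (n < 3) stop_input("need at least 3 samples to embed")
  if (is.null(perplexity)) perplexity <- min(5, (n - 1) / 3)
  perplexity <- min(perplexity, (n - 1) / 3)
  perplexity <- max(perplexity, 1.01)

  d2 <- as.matrix(stats::dist(x))^2
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) {
        hi <- beta; beta <- (lo + hi) / 2; next
      }
      pr <- w / sw
      h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      if (abs(h - log_u) < 1e-7) break
      if (h > log_u) lo <- beta else hi <- beta
      beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
    }
    p[i, -i] <- w / max(sum(w), .Machine$double.xmin)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  pc <- stats::prcomp(x, rank. = 2)$x
  if (ncol(pc) < 2) pc <- cbind(pc, 0)
  y <- pc / max(1e-12, stats::sd(pc)) * 1e-2
  y <- y + withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                            matrix(stats::rnorm(2 * n, 0, 1e-4), n, 2))

  mom <- 0.5; eta <- 100; gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  p_run <- p * 4  # early exaggeration
  for (it in seq_len(n_iter)) {
    if (it == 101) p_run <- p
    if (it == 251) mom <- 0.8
    yd2 <- as.matrix(stats::dist(y))^2
    qnum <- 1 / (1 + yd2); diag(qnum) <- 0
    q <- pmax(qnum / sum(qnum), 1e-12)
    mult <- (p_run - q) * qnum
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain <- pmax(gain, 0.01)
    inc <- mom * inc - eta * gain * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  tibble::tibble(sample = ids, tsne1 = y[, 1], tsne2 = y[, 2])
}
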