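# Array analytics: log2 summaries, DiffScore, region distributions, gene
# panels, the common-hypermethylated intersection and the funnel.

test_that("beta log2 summary matches hand arithmetic and flooring", {
  r <- beta_log2_summary(c(0.8, 0.5), c(0.4, 0.5))
  expect_equal(r$log2_ratio, c(1, 0))
  expect_equal(r$mean, 0.5)
  # identical columns: all zero
  expect_equal(beta_log2_summary(c(0.2, 0.9), c(0.2, 0.9))$mean, 0)
  # flooring keeps zero betas finite
  expect_true(is.finite(beta_log2_summary(0, 0.5)$mean))
  expect_error(beta_log2_summary(1:3 / 10, 1:2 / 10),
               class = "igem_input_error")
})

test_that("diff_score reproduces its closed-form anchor points", {
  # p = 0.05 with a positive shift: score -10*log10(0.05) = 13.0103...,
  # truncating to 13, and the strict > 13 rule does NOT call it
  d <- diff_score(0.5, 0.4, p = 0.05)
  expect_equal(d$diff_score, -10 * log10(0.05), tolerance = 1e-12)
  expect_equal(trunc(d$diff_score), 13)
  expect_false(d$hypermethylated)
  # p = 0.01 -> score 20, called
  d2 <- diff_score(0.5, 0.4, p = 0.01)
  expect_equal(d2$diff_score, 20)
  expect_true(d2$hypermethylated)
  # p = 1 -> score 0
  expect_equal(diff_score(0.5, 0.4, p = 1)$diff_score, 0)
  # antisymmetry: swapping arguments flips the sign
  a <- diff_score(c(0.7, 0.2), c(0.3, 0.6))
  b <- diff_score(c(0.3, 0.6), c(0.7, 0.2))
  expect_equal(a$diff_score, -b$diff_score)
  expect_error(diff_score(0.5, 0.4, p = 2), class = "igem_input_error")
})

test_that("noise-model p-values calibrate against the Gaussian oracle", {
  # oracle: empirical two-sided tail of delta-beta under the noise model
  sigma <- 0.03
  db <- 0.06
  emp <- withr::with_seed(11, {
    null_d <- rnorm(2e5, 0, sqrt(2) * sigma)
    mean(abs(null_d) >= db)
  })
  expect_equal(diff_score(0.5 + db, 0.5, sigma_beta = sigma)$p_value, emp,
               tolerance = 0.02)
})

test_that("region distribution sums to one per axis and flags empty calls", {
  ann <- tibble::tibble(
    probe_id = sprintf("p%d", 1:6),
    refgene_group = c("TSS200", "Body", "Body", "TSS200", "Body",
                      "intergenic"),
    cpg_context = c("island", "island", "shore", "island", "open_sea",
                    "open_sea"))
  rd <- region_distribution(tibble::tibble(probe_id = sprintf("p%d", 1:4)),
                            ann)
  expect_equal(sum(rd$cpg_context$proportion), 1)
  expect_equal(sum(rd$refgene_group$proportion), 1)
  expect_equal(rd$cpg_context$proportion[rd$cpg_context$cpg_context ==
                                           "island"], 0.75)
  rd_all <- region_distribution(tibble::tibble(probe_id = c("p1", "p2")),
                                dplyr::mutate(ann,
                                              cpg_context = "island"))
  expect_equal(rd_all$cpg_context$proportion, 1)
  rd0 <- region_distribution(tibble::tibble(probe_id = character(0)), ann)
  expect_true(attr(rd0, "empty"))
  expect_equal(nrow(rd0$cpg_context), 0)
})

test_that("gene panel methylation counts sites and handles absent genes", {
  beta <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                         trt = c(0.8, 0.4, 0.5), ctl = c(0.4, 0.4, 0.5))
  ann <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        gene = c("G1", "G1", "G2"))
  pm <- gene_panel_methylation(beta, ann, c("G1", "G2", "G3"),
                               "trt", "ctl")
  expect_equal(pm$n_sites, c(2L, 1L, 0L))
  expect_equal(pm$mean_log2_ratio[1], 0.5)
  expect_equal(pm$log2_rate_ratio[1], log2(0.6 / 0.4))
  expect_equal(pm$mean_log2_ratio[2], 0)
  expect_true(is.na(pm$mean_log2_ratio[3]))
})

test_that("common hypermethylated genes require the fold threshold in both", {
  a <- tibble::tibble(gene = c("X", "Y", "Z"), fold_change = c(12, 15, 9))
  b <- tibble::tibble(gene = c("X", "Z", "W"), fold_change = c(11, 20, 30))
  expect_equal(common_hyper_genes(a, b), "X")
  # identical call sets intersect to themselves
  expect_equal(common_hyper_genes(a, a), c("X", "Y"))
  # disjoint sets are empty
  expect_length(common_hyper_genes(a[1, ], b[3, ]), 0)
  # boundary: exactly 10 is not "more than 10"
  expect_length(common_hyper_genes(
    tibble::tibble(gene = "X", fold_change = 10),
    tibble::tibble(gene = "X", fold_change = 10)), 0)
})

test_that("planted methylome structure is recovered end to end", {
  cfg <- small_cfg(seed = 31, n_probes = 20000L)
  bm <- sim_beta_matrix(cfg)
  ds <- list(
    etoposide = diff_score(bm$beta$etoposide, bm$beta$control),
    propyl_gallate = diff_score(bm$beta$propyl_gallate, bm$beta$control))
  # called sites are island-dominated for a hyper agent
  called <- dplyr::bind_cols(bm$beta["probe_id"],
                             ds$etoposide)[ds$etoposide$hypermethylated, ]
  rd <- region_distribution(called, bm$annotation)
  isl_prop <- rd$cpg_context$proportion[rd$cpg_context$cpg_context ==
                                          "island"]
  expect_gt(isl_prop, 0.9)
  # a null agent calls (almost) nothing
  ds_null <- diff_score(bm$beta$theophylline, bm$beta$control)
  expect_lt(sum(ds_null$hypermethylated), 10)
  # the strong promoter set yields exactly the 12 planted common genes
  fc_calls <- purrr::imap(ds, function(d, tr) {
    cl <- dplyr::bind_cols(bm$beta["probe_id"], d) |>
      dplyr::filter(.data$hypermethylated) |>
      dplyr::inner_join(bm$annotation, by = "probe_id")
    i <- match(cl$probe_id, bm$beta$probe_id)
    dplyr::mutate(cl, fold_change = pmax(bm$beta[[tr]][i], 1e-3) /
                    pmax(bm$beta$control[i], 1e-3))
  })
  common <- common_hyper_genes(fc_calls$etoposide,
                               fc_calls$propyl_gallate)
  expect_equal(common,
               sort(igemscreen:::strong_hyper_sets()$common))
})

test_that("funnel recovers the planted 28/16/9 and its trivial cases", {
  cfg <- small_cfg(seed = 37, n_probes = 20000L)
  bm <- sim_beta_matrix(cfg)
  pm <- lapply(c(e = "etoposide", p = "propyl_gallate"), function(tr)
    gene_panel_methylation(bm$beta, bm$annotation, cfg$panel_genes, tr,
                           "control"))
  ex <- sim_expression(cfg, bm$truth)
  ea <- expression_analysis(ex$rpkm)
  fn <- methylation_expression_funnel(ea$common_down, pm$e, pm$p)
  expect_equal(c(fn$n_down, fn$n_meth_either, fn$n_meth_both),
               c(28L, 16L, 9L))
  expect_setequal(fn$meth_both, cfg$panel_genes[1:9])
  # no methylation change anywhere: counts (n, 0, 0)
  flat <- dplyr::mutate(pm$e, mean_log2_ratio = 0, log2_rate_ratio = 0)
  fn0 <- methylation_expression_funnel(ea$common_down, flat, flat)
  expect_equal(c(fn0$n_down, fn0$n_meth_either, fn0$n_meth_both),
               c(28L, 0L, 0L))
  # empty common-down: all zero
  fn_e <- methylation_expression_funnel(character(0), pm$e, pm$p)
  expect_equal(fn_e$n_down, 0L)
})

test_that("tsne embedding is deterministic and groups the hyper agents", {
  cfg <- small_cfg(seed = 41, n_probes = 6000L)
  bm <- sim_beta_matrix(cfg)
  trs <- setdiff(names(bm$beta), c("probe_id", "control"))
  prof <- vapply(trs, function(tr)
    beta_log2_summary(bm$beta[[tr]], bm$beta$control)$log2_ratio,
    numeric(nrow(bm$beta)))
  e1 <- tsne_embed(t(prof), seed = 3)
  expect_identical(e1, tsne_embed(t(prof), seed = 3))
  d <- as.matrix(dist(as.matrix(e1[c("tsne1", "tsne2")])))
  dimnames(d) <- list(e1$sample, e1$sample)
  hyper <- c("biotin", "etoposide", "propyl_gallate")
  other <- setdiff(trs, hyper)
  within <- d[hyper, hyper][upper.tri(diag(3))]
  between <- as.vector(d[hyper, other])
  expect_lt(mean(within), mean(between))
  # duplicated samples end up as the closest pair
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
             c = c(9, 1, 0, 2), d = c(5, 5, 5, 5))
  e2 <- tsne_embed(x, seed = 1)
  dd <- as.matrix(dist(as.matrix(e2[c("tsne1", "tsne2")])))
  expect_equal(dd[1, 2], min(dd[dd > 0]))
  expect_error(tsne_embed(x[1:2, ], seed = 1), class = "igem_input_error")
})

test_that("expression analysis forms fold changes and the common-down set", {
  rpkm <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         control = c(10, 20, 0),
                         etoposide = c(5, 30, 4),
                         propyl_gallate = c(8, 10, 4))
  ea <- expression_analysis(rpkm)
  expect_equal(ea$common_down, "g1")
  expect_equal(ea$zero_control_genes, "g3")
  expect_equal(ea$fold_change$etoposide, c(0.5, 1.5))
  # treated == control: all fold changes 1, nothing down
  same <- tibble::tibble(gene = c("g1", "g2"), control = c(5, 5),
                         etoposide = c(5, 5), propyl_gallate = c(5, 5))
  ea2 <- expression_analysis(same)
  expect_true(all(as.matrix(ea2$fold_change[-1]) == 1))
  expect_length(ea2$common_down, 0)
  # planted set recovered exactly
  cfg <- small_cfg(seed = 43)
  ex <- sim_expression(cfg)
  ea3 <- expression_analysis(ex$rpkm)
  expect_setequal(ea3$common_down, ex$truth$down_both)
})
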