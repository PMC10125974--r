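# Synthetic-data generators: determinism, invariants, planted structure.

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(image_size = c(0, 10)), class = "igem_config_error")
  expect_error(sim_config(nucleus_radius_px = c(-1, 1)),
               class = "igem_config_error")
  expect_error(sim_config(category_proportions = c(0.5, 0.2, 0.2)),
               class = "igem_config_error")
  expect_error(sim_config(background_noise_sd = -1),
               class = "igem_config_error")
  expect_error(sim_config(panel_genes = c("A", "B")),
               class = "igem_config_error")
})

test_that("every generator is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 7)
  expect_identical(sim_screen_table(cfg), sim_screen_table(cfg))
  expect_identical(sim_activity_db(cfg), sim_activity_db(cfg))
  cfg_small <- small_cfg(seed = 7, n_probes = 3000L, rrbs_n_sites = 2000L)
  expect_identical(sim_beta_matrix(cfg_small), sim_beta_matrix(cfg_small))
  expect_identical(sim_rrbs_calls(cfg_small), sim_rrbs_calls(cfg_small))
  expect_identical(sim_expression(cfg_small), sim_expression(cfg_small))
  expect_identical(sim_plate_images(cfg, "control"),
                   sim_plate_images(cfg, "control"))
})

test_that("screen table plants exact category counts and noise-free means", {
  cfg <- small_cfg(seed = 3)
  s <- sim_screen_table(cfg)
  expect_equal(nrow(s$table), 135)
  expect_equal(unname(table(s$truth$category)[c("A", "B", "C")]),
               c(63L, 36L, 36L), ignore_attr = TRUE)
  # zero noise: every chemical sits exactly on its category mean
  s0 <- sim_screen_table(small_cfg(seed = 3, screen_noise_sd = 0))
  b_rows <- s0$table[s0$truth$category == "B", ]
  expect_true(all(abs(b_rows$foci_intensity -
                        igemscreen:::.category_means$B[["foci_intensity"]]) <
                    1e-12))
  expect_true(all(s0$table$foci_intensity > 0))
})

test_that("plate image generator honours effect multipliers in ground truth", {
  cfg <- small_cfg(seed = 2)
  w <- sim_plate_images(cfg, "control")
  expect_length(w$fields, 2)
  expect_equal(dim(w$fields[[1]]$nuclei), cfg$image_size)
  # deterministic seeding: every field holds the configured nucleus count
  expect_equal(nrow(w$truth), 2 * cfg$n_nuclei_per_field)
  # zero count multiplier: red channel is background + nuclei only
  cfg0 <- small_cfg(seed = 2, effect_multipliers = tibble::tibble(
    chemical_id = "nofoci", foci_intensity = 1, foci_area = 1,
    foci_count = 0, nuclei = 1))
  w0 <- sim_plate_images(cfg0, "nofoci")
  expect_true(all(w0$truth$n_foci == 0))
  expect_lt(max(w0$fields[[1]]$mbd), cfg0$mbd_background + 8 * 10)
  expect_error(sim_plate_images(cfg, "unknown_chemical"),
               class = "igem_config_error")
})

test_that("activity snapshot uses closed vocabularies and plants 114 labelled", {
  cfg <- small_cfg(seed = 11)
  db <- sim_activity_db(cfg)
  expect_setequal(unique(db$genetox$outcome), c("positive", "negative"))
  expect_true(all(db$iarc$group %in% c("1", "2A", "2B", "3", "4")))
  expect_true(all(db$tox21$outcome %in%
                    c("active", "inconclusive", "inactive", "none")))
  expect_length(attr(db$truth, "labeled_ids"), 114)
  # chemicals without records appear in no table
  absent <- setdiff(db$registry$chemical_id, attr(db$truth, "labeled_ids"))
  for (tab in db[c("genetox", "ccris", "iarc", "tox21")]) {
    expect_length(intersect(absent, tab$chemical_id), 0)
  }
})

test_that("beta matrix is bounded with island-concentrated effects", {
  cfg <- small_cfg(seed = 5, n_probes = 8000L)
  bm <- sim_beta_matrix(cfg)
  b <- as.matrix(bm$beta[-1])
  expect_true(all(b >= 0 & b <= 1))
  # zero effect: treated columns equal control up to measurement noise
  bm0 <- sim_beta_matrix(small_cfg(seed = 5, n_probes = 8000L,
                                   beta_effect = 0, beta_noise_sd = 0))
  expect_equal(bm0$beta$etoposide, bm0$beta$control)
  # island log2 gain exceeds open-sea gain for a hyper agent
  ls <- beta_log2_summary(bm$beta$etoposide, bm$beta$control)
  isl <- bm$annotation$cpg_context == "island" & bm$annotation$gene == ""
  sea <- bm$annotation$cpg_context == "open_sea"
  expect_gt(mean(ls$log2_ratio[isl]), mean(ls$log2_ratio[sea]))
  expect_gt(ls$mean, 0)
})

test_that("rrbs calls respect count bounds and the coverage distribution", {
  cfg <- small_cfg(seed = 9, rrbs_n_sites = 12000L)
  rr <- sim_rrbs_calls(cfg)
  for (s in rr$calls) {
    expect_true(all(s$n_meth <= s$coverage))
    expect_true(all(s$n_meth >= 0))
  }
  # fraction of background sites under 10x matches the NB CDF at 9
  bg <- rr$calls$control[seq_len(cfg$rrbs_n_sites - 9 * 40), ]
  expect_equal(mean(bg$coverage < 10),
               pnbinom(9, size = cfg$rrbs_dispersion,
                       mu = cfg$rrbs_mean_coverage),
               tolerance = 0.02)
  # the nine tracked genes map to disjoint chr1 intervals
  expect_equal(nrow(rr$gene_map), 9)
  expect_true(all(rr$gene_map$start < rr$gene_map$end))
})

test_that("expression panel has 100 genes and plants the common-down set", {
  cfg <- small_cfg(seed = 4)
  ex <- sim_expression(cfg)
  expect_equal(nrow(ex$rpkm), 100)
  expect_true(all(as.matrix(ex$rpkm[-1]) >= 0))
  expect_length(ex$truth$down_both, 28)
  expect_true(all(ex$truth$fold_change[ex$truth$down_both, "etoposide"] < 1))
  expect_true(all(ex$truth$fold_change[ex$truth$down_both,
                                       "propyl_gallate"] < 1))
})
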