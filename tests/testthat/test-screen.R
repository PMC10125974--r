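# Control normalisation, viability gate, clustering, category calls and
# the screen's test statistics.

mk_measures <- function(int, area = 8, count = 2, nuclei = 100) {
  tibble::tibble(nuclei_count = nuclei,
                 foci_intensity_per_nucleus = int,
                 foci_area_per_nucleus = area,
                 foci_count_per_nucleus = count)
}

test_that("ratio_to_control divides replicate means and propagates SE", {
  t <- mk_measures(c(90, 100, 110))
  c0 <- mk_measures(c(200, 200, 200))
  r <- ratio_to_control(t, c0)
  expect_equal(r$ratio[r$parameter == "foci_intensity"], 0.5)
  expect_equal(r$ratio[r$parameter == "nuclei"], 1)
  # identical arms: all ratios exactly 1
  r1 <- ratio_to_control(c0, c0)
  expect_equal(r1$ratio, rep(1, 4))
  # scale equivariance: scaling treated scales the ratio
  r3 <- ratio_to_control(mk_measures(3 * c(90, 100, 110)), c0)
  expect_equal(r3$ratio[r3$parameter == "foci_intensity"], 1.5)
  # zero control errors and names the parameter
  bad <- mk_measures(c(200, 200), count = 0)
  expect_error(ratio_to_control(t[1:2, ], bad), "foci_count")
})

test_that("viability gate is inclusive at the boundary", {
  tab <- tibble::tibble(chemical_id = c("a", "b", "c"),
                        nuclei = c(0.69, 0.70, 1.2))
  g <- viability_gate(tab)
  expect_equal(g$viable, c(FALSE, TRUE, TRUE))
  expect_equal(nrow(viability_gate(tab[0, ])), 0)
})

test_that("clustering separates archetypal profiles and is order-invariant", {
  tab <- tibble::tibble(
    chemical_id = c("lo", "hi", "null"),
    foci_intensity = c(0.6, 1.4, 1.01),
    foci_area = c(0.6, 1.4, 0.99),
    foci_count = c(0.6, 1.4, 1.0),
    nuclei = c(1.2, 0.8, 1.0)
  )
  cl <- cluster_chemicals(tab, k = 3)
  expect_equal(dplyr::n_distinct(cl$clusters$cluster_id), 3)
  # permuting rows gives the same partition
  perm <- tab[c(3, 1, 2), ]
  cl2 <- cluster_chemicals(perm, k = 3)
  j <- dplyr::inner_join(cl$clusters, cl2$clusters, by = "chemical_id")
  tab1 <- table(j$cluster_id.x, j$cluster_id.y)
  expect_true(all(rowSums(tab1 > 0) == 1))
  # constant profile is a hard error naming the row
  tab$foci_intensity[1] <- 0.6; tab$nuclei[1] <- 0.6
  tab$foci_area[1] <- 0.6; tab$foci_count[1] <- 0.6
  expect_error(cluster_chemicals(tab, k = 3), "lo")
  # newick export is parseable
  nwk <- cluster_newick(cl)
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("synthetic screen clustering matches ground truth exactly", {
  cfg <- small_cfg(seed = 21)
  s <- sim_screen_table(cfg)
  cl <- cluster_chemicals(viability_gate(s$table), k = 3)
  cats <- assign_categories(cl)
  j <- dplyr::inner_join(cats, s$truth, by = "chemical_id")
  expect_equal(mean(j$category.x == j$category.y), 1)
  expect_equal(unname(table(cats$category)[c("A", "B", "C")]),
               c(63L, 36L, 36L), ignore_attr = TRUE)
})

test_that("category labels follow the cluster mean profiles", {
  tab <- tibble::tibble(
    chemical_id = c("e", "z", "c"),
    foci_intensity = c(1.37, 0.56, 1.01),
    foci_area = c(1.35, 0.56, 0.99),
    foci_count = c(1.34, 0.63, 1.0),
    nuclei = c(0.9, 1.15, 1.0)
  )
  cats <- assign_categories(cluster_chemicals(tab, k = 3))
  expect_equal(cats$category[cats$chemical_id == "e"], "B")
  expect_equal(cats$category[cats$chemical_id == "z"], "A")
  expect_equal(cats$category[cats$chemical_id == "c"], "C")
})

test_that("dose response ANOVA and Tukey behave at the extremes", {
  # identical groups: F ~ 0, p ~ 1
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("d1", "d2", "d3"), each = 3)
  r <- dose_response_test(v, g)
  expect_lt(r$anova$statistic, 1e-20)
  expect_gt(r$anova$p_value, 0.999)
  # strong separation: closed-form F is huge, both p's < 1e-3
  withr::with_seed(8, {
    v2 <- c(rnorm(10, 0, 1), rnorm(10, 5, 1))
    g2 <- rep(c("ctrl", "dose"), each = 10)
  })
  r2 <- dose_response_test(v2, g2)
  # with two groups the ANOVA F equals the pooled two-sample t^2
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(r2$anova$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_lt(r2$anova$p_value, 1e-3)
  expect_lt(r2$pairwise$p_value, 1e-3)
})

test_that("steel_dwass matches its extremes and the k = 2 rank-sum case", {
  g <- rep(c("a", "b", "c"), each = 8)
  # three identical groups: all pairwise p ~ 1
  expect_true(all(steel_dwass(rep(1:8, 3), g)$p_value >= 0.99))
  # fully separated groups: all pairwise p < 0.01
  expect_true(all(steel_dwass(c(1:8, 11:18, 21:28), g)$p_value < 0.01))
  # k = 2 equals the tie-corrected normal Wilcoxon within 1e-6
  withr::with_seed(3, {
    x <- rnorm(10); y <- rnorm(12, 0.6)
  })
  p_sd <- steel_dwass(c(x, y), rep(c("x", "y"), c(10, 12)))$p_value
  p_w <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_sd, p_w, tolerance = 1e-6)
  # ties are handled through the corrected variance
  p_tie <- steel_dwass(c(1, 1, 2, 2, 3, 3, 4, 4),
                       rep(c("a", "b"), 4))$p_value
  expect_true(p_tie >= 0 && p_tie <= 1)
  expect_error(steel_dwass(1:5, c("a", "a", "b", "b", "c")),
               class = "igem_input_error")
})

test_that("steel_dwass tracks the joint-permutation distribution", {
  # tails: the separated example agrees within 0.01
  v <- c(1:8, 11:18, 21:28)
  g <- rep(c("a", "b", "c"), each = 8)
  p_an <- steel_dwass(v, g)$p_value
  p_perm <- steel_dwass_perm_oracle(v, g, B = 4000)
  expect_true(all(abs(p_an - p_perm) < 0.01))
  # mid-range p at n = 8 per group: the normal/studentized-range
  # approximation is liberal by up to a few hundredths
  withr::with_seed(5, {
    v2 <- c(rnorm(8), rnorm(8, 1.2), rnorm(8, 0.5))
  })
  p_an2 <- steel_dwass(v2, g)$p_value
  p_perm2 <- steel_dwass_perm_oracle(v2, g, B = 4000)
  expect_true(all(abs(p_an2 - p_perm2) < 0.06))
})
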