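# Synthetic EPIC-style beta matrix, RRBS call tables and targeted panel
# expression, all with planted ground truth.

beta_samples <- c("control", "biotin", "etoposide", "propyl_gallate",
                  "theophylline", "bisphenol_a")
hyper_agents <- c("biotin", "etoposide", "propyl_gallate")
rrbs_samples <- c("control", "etoposide", "propyl_gallate", "theophylline",
                  "aza_dc")

# Non-panel genes carrying very strong promoter hypermethylation (control
# beta near zero, treated ~0.45, so the beta fold change exceeds 10): twelve
# shared by both focal agents, five specific to each.
strong_hyper_sets <- function() {
  list(
    common = c("BRCA1", "MLH1", "CDH13", "RASSF1", "GSTP1", "MGMT",
               "DAPK1", "APC", "VHL", "CDKN2B", "PTEN", "TIMP3"),
    etoposide = c("SFRP1", "SFRP2", "WIF1", "DKK1", "SOX15"),
    propyl_gallate = c("TWIST1", "CDH4", "HIC1", "PYCARD", "RARB")
  )
}

# Planted panel gene sets: the first 28 panel genes are repressed by both
# focal hypermethylation agents; of those, genes 1-9 gain promoter
# methylation under both agents, genes 10-13 under etoposide only and
# 14-16 under propyl gallate only.
panel_gene_sets <- function(panel) {
  list(
    down_both = panel[1:28],
    meth_both = panel[1:9],
    meth_etoposide_only = panel[10:13],
    meth_pg_only = panel[14:16],
    meth_either = panel[1:16],
    rrbs_confirm = c("JAG1", "LIFR", "CCND2", "RB1")
  )
}

#' Simulate an EPIC-style beta-value matrix with probe annotation
#'
#' Control beta values follow the U-shaped bimodal mixture characteristic of
#' Infinium arrays (Beta(0.5,8) and Beta(8,0.5) components, islands biased
#' low).  Hypermethylation agents (biotin, etoposide, propyl gallate) gain
#' `cfg$beta_effect` at background CpG-island probes; etoposide and propyl
#' gallate additionally gain methylation at the planted panel-gene promoters
#' and drive a set of strong (>10-fold) promoter gains used downstream for
#' the common-hypermethylated-gene intersection.  All samples carry
#' independent Gaussian measurement noise and are clipped to [0,1].
#'
#' @param cfg An [sim_config()] object.
#' @return List with `beta` (tibble: `probe_id` + one column per sample),
#'   `annotation` (tibble: `probe_id`, `chromosome`, `position`, `gene`,
#'   `refgene_group`, `cpg_context`) and `truth` (planted deltas and gene
#'   sets).
#' @export
sim_beta_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "igem_sim_config"))
  panel <- cfg$panel_genes
  sets <- panel_gene_sets(panel)
  strong <- strong_hyper_sets()
  with_gen_seed(cfg$seed, .gen_offsets[["beta"]], code = {
    probes_per_gene <- 12L
    strong_genes <- unlist(strong, use.names = FALSE)
    n_panel <- length(panel) * probes_per_gene
    n_strong <- length(strong_genes) * 3L
    n_bg <- cfg$n_probes - n_panel - n_strong
    if (n_bg < 0) stop_config("`n_probes` too small for the planted gene sets")

    ann <- dplyr::bind_rows(
      tibble::tibble(
        gene = rep(panel, each = probes_per_gene),
        refgene_group = sample(c("TSS1500", "TSS200", "5'UTR"), n_panel,
                               replace = TRUE, prob = c(0.4, 0.4, 0.2)),
        cpg_context = sample(c("island", "shore"), n_panel,
                             replace = TRUE, prob = c(0.3, 0.7)),
        kind = "panel"
      ),
      tibble::tibble(
        gene = rep(strong_genes, each = 3L),
        refgene_group = "TSS200",
        cpg_context = "island",
        kind = "strong"
      ),
      tibble::tibble(
        gene = "",
        refgene_group = sample(
          c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR",
            "intergenic"),
          n_bg, replace = TRUE,
          prob = c(0.06, 0.05, 0.05, 0.04, 0.35, 0.05, 0.40)),
        cpg_context = sample(
          c("island", "shore", "shelf", "open_sea"), n_bg, replace = TRUE,
          prob = c(cfg$island_fraction, 0.18, 0.12,
                   max(0, 0.70 - cfg$island_fraction))),
        kind = "background"
      )
    ) |>
      dplyr::mutate(
        probe_id = sprintf("cg%08d", seq_len(cfg$n_probes)),
        chromosome = sample(paste0("chr", 1:22), cfg$n_probes, replace = TRUE),
        position = sample.int(5e7, cfg$n_probes, replace = TRUE)
      ) |>
      dplyr::select("probe_id", "chromosome", "position", "gene",
                    "refgene_group", "cpg_context", "kind")

    # baseline methylation: promoters of panel genes intermediate-low,
    # strong-set promoters nearly unmethylated, background U-shaped
    base <- numeric(cfg$n_probes)
    is_panel <- ann$kind == "panel"
    is_strong <- ann$kind == "strong"
    is_bg <- ann$kind == "background"
    # panel promoters sit at intermediate-low methylation, floored away
    # from zero so their planted +beta_effect gains stay well below the
    # >10-fold band reserved for the strong promoter set
    base[is_panel] <- pmax(stats::rbeta(sum(is_panel), 3, 9), 0.05)
    base[is_strong] <- stats::runif(sum(is_strong), 0.01, 0.04)
    low <- stats::rbeta(sum(is_bg), 0.5, 8)
    high <- stats::rbeta(sum(is_bg), 8, 0.5)
    p_low <- ifelse(ann$cpg_context[is_bg] == "island", 0.85, 0.20)
    base[is_bg] <- ifelse(stats::runif(sum(is_bg)) < p_low, low, high)

    # planted deltas per sample
    delta <- matrix(0, cfg$n_probes, length(beta_samples),
                    dimnames = list(ann$probe_id, beta_samples))
    bg_island <- is_bg & ann$cpg_context == "island"
    for (ag in hyper_agents) delta[bg_island, ag] <- cfg$beta_effect
    gene_rows <- function(gs) ann$gene %in% gs
    for (ag in c("etoposide", "propyl_gallate")) {
      meth_genes <- switch(ag,
        etoposide = c(sets$meth_both, sets$meth_etoposide_only),
        propyl_gallate = c(sets$meth_both, sets$meth_pg_only))
      delta[is_panel & gene_rows(meth_genes), ag] <- cfg$beta_effect
      # the strong promoter set is part of the hypermethylation response;
      # a zero beta_effect disables every planted gain
      strong_genes_ag <- c(strong$common, strong[[ag]])
      delta[is_strong & gene_rows(strong_genes_ag), ag] <-
        if (cfg$beta_effect > 0) 0.42 else 0
    }

    beta <- vapply(beta_samples, function(s) {
      pmin(pmax(base + delta[, s] +
                  stats::rnorm(cfg$n_probes, 0, cfg$beta_noise_sd), 0), 1)
    }, numeric(cfg$n_probes))
    beta_tbl <- dplyr::bind_cols(tibble::tibble(probe_id = ann$probe_id),
                                 tibble::as_tibble(beta))
    list(
      beta = beta_tbl,
      annotation = dplyr::select(ann, -"kind"),
      truth = list(
        base = base,
        delta = delta,
        gene_sets = c(sets, list(strong = strong)),
        hyper_agents = hyper_agents
      )
    )
  })
}

#' Simulate per-cytosine RRBS call tables
#'
#' Coverage is negative-binomial around `cfg$rrbs_mean_coverage` with a
#' small admixture of PCR-artifact-like sites at ~12x coverage (so the
#' 99.9th-percentile filter has something to remove); methylated counts are
#' binomial given the site's methylation fraction.  Etoposide and propyl
#' gallate gain methylation globally (+0.05) and strongly (+0.25) at the
#' planted confirmation genes; 5-aza-dC scales methylation down globally.
#'
#' @param cfg An [sim_config()] object.
#' @return List with `calls` (named list of per-sample tibbles: `chrom`,
#'   `pos`, `strand`, `coverage`, `n_meth`), `gene_map` (tibble mapping the
#'   nine panel genes to genomic intervals) and `truth`.
#' @export
sim_rrbs_calls <- function(cfg) {
  stopifnot(inherits(cfg, "igem_sim_config"))
  sets <- panel_gene_sets(cfg$panel_genes)
  genes9 <- cfg$panel_genes[1:9]
  with_gen_seed(cfg$seed, .gen_offsets[["rrbs"]], code = {
    n <- cfg$rrbs_n_sites
    # unique site coordinates per chromosome, as in a real call table
    chrom <- sort(sample(paste0("chr", 1:5), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_along(chrom), chrom), function(i) {
      sort(sample.int(2e6, length(i)))
    }), use.names = FALSE)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # reserve one 5-kb block per tracked gene on chr1 and pin 15 sites there
    gene_map <- tibble::tibble(
      gene = genes9,
      chrom = "chr1",
      start = 3e6 + (seq_along(genes9) - 1L) * 10000L + 1L,
      end = 3e6 + (seq_along(genes9) - 1L) * 10000L + 5000L
    )
    sites_per_gene <- 40L
    gene_idx <- list()
    for (i in seq_along(genes9)) {
      idx <- (n - sites_per_gene * i + 1):(n - sites_per_gene * (i - 1))
      chrom[idx] <- "chr1"
      pos[idx] <- sort(sample(gene_map$start[i]:gene_map$end[i],
                              sites_per_gene))
      gene_idx[[genes9[i]]] <- idx
    }

    frac0 <- ifelse(stats::runif(n) < 0.8,
                    pmin(pmax(stats::rnorm(n, 0.85, 0.05), 0), 1),
                    pmin(pmax(stats::rnorm(n, 0.10, 0.04), 0), 1))
    for (g in genes9) {
      frac0[gene_idx[[g]]] <- stats::runif(sites_per_gene, 0.25, 0.35)
    }

    # planted per-gene gains: four confirmed by both agents, the rest by one
    # or neither
    gain <- list(
      etoposide = c(sets$rrbs_confirm, "NOTCH4", "CCNA2"),
      propyl_gallate = c(sets$rrbs_confirm, "SMAD4", "JUND")
    )
    frac_for <- function(sample_id) {
      f <- frac0
      if (sample_id %in% c("etoposide", "propyl_gallate")) {
        # global drift on background sites only; the tracked gene blocks
        # move solely through their planted per-gene gains so the
        # confirmation set is exactly the planted one
        f <- pmin(f + 0.05, 1)
        for (g in genes9) f[gene_idx[[g]]] <- frac0[gene_idx[[g]]]
        for (g in gain[[sample_id]]) {
          f[gene_idx[[g]]] <- pmin(frac0[gene_idx[[g]]] + 0.25, 1)
        }
      } else if (sample_id == "aza_dc") {
        f <- f * 0.6
      }
      f
    }

    calls <- lapply(rrbs_samples, function(s) {
      cov <- stats::rnbinom(n, size = cfg$rrbs_dispersion,
                            mu = cfg$rrbs_mean_coverage)
      spike <- stats::runif(n) < 0.002
      cov[spike] <- cov[spike] * 12L
      # promoter blocks are RRBS-enriched: double coverage at tracked genes
      cov[unlist(gene_idx)] <- cov[unlist(gene_idx)] * 2L
      f <- frac_for(s)
      tibble::tibble(
        chrom = chrom, pos = pos, strand = strand,
        coverage = as.integer(cov),
        n_meth = stats::rbinom(n, cov, f)
      )
    })
    names(calls) <- rrbs_samples
    list(
      calls = calls,
      gene_map = gene_map,
      truth = list(
        frac0 = frac0,
        gene_gain = gain,
        confirm_both = sets$rrbs_confirm
      )
    )
  })
}

#' Simulate the 100-gene targeted expression panel (RPKM)
#'
#' Baseline RPKM is log-normal.  Under the two focal hypermethylation agents
#' the planted repressed genes get true fold changes in (0.3, 0.8) while all
#' remaining panel genes get mildly induced fold changes in (1.15, 1.5),
#' emulating the bimodal response of a stress-exposed targeted panel and
#' keeping "decreased" well separated from measurement noise.  Other
#' treatments fluctuate around 1.
#'
#' @param cfg An [sim_config()] object.
#' @param methylation_truth Optional `truth` element from
#'   [sim_beta_matrix()]; its `gene_sets$down_both` overrides the default
#'   planted repressed set.
#' @return List with `rpkm` (tibble: `gene` + one column per sample) and
#'   `truth` (true fold-change tibble and the planted common-down set).
#' @export
sim_expression <- function(cfg, methylation_truth = NULL) {
  stopifnot(inherits(cfg, "igem_sim_config"))
  panel <- cfg$panel_genes
  down <- if (!is.null(methylation_truth)) {
    methylation_truth$gene_sets$down_both
  } else {
    panel_gene_sets(panel)$down_both
  }
  with_gen_seed(cfg$seed, .gen_offsets[["expression"]], code = {
    base <- stats::rlnorm(length(panel), log(50), 1)
    fc <- matrix(1, length(panel), length(beta_samples),
                 dimnames = list(panel, beta_samples))
    for (ag in c("etoposide", "propyl_gallate")) {
      fc[, ag] <- stats::runif(length(panel), 1.15, 1.5)
      fc[panel %in% down, ag] <- stats::runif(sum(panel %in% down), 0.3, 0.8)
    }
    fc[, "biotin"] <- stats::runif(length(panel), 0.9, 1.3)
    fc[panel %in% down[1:10], "biotin"] <-
      stats::runif(10, 0.5, 0.9)
    for (s in c("theophylline", "bisphenol_a")) {
      fc[, s] <- exp(stats::rnorm(length(panel), 0, 0.08))
    }
    rpkm <- vapply(beta_samples, function(s) {
      noise <- exp(stats::rnorm(length(panel), 0, cfg$rpkm_noise_sd))
      base * fc[, s] * noise
    }, numeric(length(panel)))
    list(
      rpkm = dplyr::bind_cols(tibble::tibble(gene = panel),
                              tibble::as_tibble(rpkm)),
      truth = list(fold_change = fc, down_both = down)
    )
  })
}
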