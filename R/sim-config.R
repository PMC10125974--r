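#' Simulation configuration for the synthetic screening study
#'
#' Builds the configuration object consumed by all `sim_*()` generators.
#' Defaults emulate the study design that the pipeline targets: a 135-chemical
#' screen read out as nine imaging fields per 96-well plate well, three latent
#' methylation categories of sizes 63/36/36 (hypo-, hyper-, and intermediate
#' agents), 114 of the 135 chemicals carrying toxicology-database records, an
#' EPIC-style beta-value matrix with hypermethylation effects concentrated at
#' CpG islands, RRBS-style per-cytosine counts, and a 100-gene stemness
#' expression panel anti-correlated with gene-level promoter methylation.
#'
#' @param seed Integer master seed. Every generator derives its own stream
#'   from this seed plus a stable per-generator offset, so a fixed seed gives
#'   byte-identical outputs and adding one generator never perturbs another.
#' @param n_fields_per_well Imaging fields acquired per well (1--9).
#' @param image_size Integer vector of length 2, field size in pixels.
#' @param n_nuclei_per_field Mean number of nuclei seeded per field.
#' @param nucleus_radius_px Length-2 vector, mean and sd of nucleus radius.
#' @param foci_per_nucleus Poisson mean of true MBD foci per nucleus.
#' @param focus_radius_px Gaussian sigma (px) of a rendered focus.
#' @param focus_amplitude Peak intensity of a focus above the nuclear
#'   background, arbitrary units.
#' @param mbd_background Diffuse red-channel intensity inside nuclei.
#' @param nucleus_amplitude Blue-channel intensity of a nucleus interior.
#' @param background_noise_sd Additive Gaussian noise sd on both channels.
#' @param seeding_cv Coefficient of variation of the per-field nucleus count
#'   (0 = deterministic seeding; plate-to-plate seeding variability is not
#'   reported for the assay, so it is exposed rather than fixed).
#' @param effect_multipliers Tibble with columns `chemical_id`,
#'   `foci_intensity`, `foci_area`, `foci_count`, `nuclei`: multiplicative
#'   shifts a "treatment" applies to the true per-nucleus parameters. The
#'   default rows carry the control (all 1), an etoposide-like
#'   hypermethylation agent (1.37, 1.35, 1.34, 0.9) and a 5-aza-dC-like
#'   hypomethylation agent (0.56, 0.56, 0.63, 1.15).
#' @param n_chemicals Number of chemicals in the screen table.
#' @param category_proportions Proportions of categories A/B/C; must sum to 1.
#' @param screen_noise_sd Gaussian noise sd on the per-chemical ratios.
#' @param n_with_records Number of chemicals given at least one database
#'   record (the labelled subset).
#' @param n_activities Number of harmonised activities (including
#'   genotoxicity and carcinogenicity).
#' @param n_probes Number of array probes simulated.
#' @param island_fraction Fraction of background probes in CpG islands.
#' @param beta_effect Planted increase in beta at affected probes for
#'   hypermethylation agents.
#' @param beta_noise_sd Per-probe measurement noise sd on beta.
#' @param rrbs_n_sites Number of RRBS cytosines per sample.
#' @param rrbs_mean_coverage Mean read coverage of an RRBS site.
#' @param rrbs_dispersion Negative-binomial size parameter of RRBS coverage
#'   (smaller = heavier right tail).
#' @param panel_genes Character vector of the 100 expression-panel genes.
#' @param rpkm_noise_sd Log-scale measurement noise sd on panel RPKM.
#'
#' @return A list of class `igem_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$category_counts
sim_config <- function(seed = 1L,
                       n_fields_per_well = 9L,
                       image_size = c(256L, 256L),
                       n_nuclei_per_field = 8L,
                       nucleus_radius_px = c(16, 1.5),
                       foci_per_nucleus = 3,
                       focus_radius_px = 1.0,
                       focus_amplitude = 600,
                       mbd_background = 60,
                       nucleus_amplitude = 400,
                       background_noise_sd = 10,
                       seeding_cv = 0,
                       effect_multipliers = default_effect_multipliers(),
                       n_chemicals = 135L,
                       category_proportions = c(A = 63, B = 36, C = 36) / 135,
                       screen_noise_sd = 0.02,
                       n_with_records = 114L,
                       n_activities = 50L,
                       n_probes = 50000L,
                       island_fraction = 0.25,
                       beta_effect = 0.2,
                       beta_noise_sd = 0.01,
                       rrbs_n_sites = 20000L,
                       rrbs_mean_coverage = 30,
                       rrbs_dispersion = 5,
                       panel_genes = stem_panel_genes(),
                       rpkm_noise_sd = 0.05) {
  if (length(image_size) != 2 || any(image_size <= 0)) {
    stop_config("`image_size` must be two positive integers")
  }
  if (any(nucleus_radius_px <= 0)) {
    stop_config("`nucleus_radius_px` mean and sd must be positive")
  }
  if (abs(sum(category_proportions) - 1) > 1e-9) {
    stop_config("`category_proportions` must sum to 1")
  }
  nonneg <- c(foci_per_nucleus, focus_radius_px, focus_amplitude,
              mbd_background, background_noise_sd, screen_noise_sd,
              beta_effect, beta_noise_sd, rrbs_mean_coverage, rpkm_noise_sd)
  if (any(nonneg < 0)) {
    stop_config("intensity, noise and coverage parameters must be non-negative")
  }
  if (n_chemicals < 3) stop_config("`n_chemicals` must be at least 3")
  if (length(panel_genes) != 100) {
    stop_config("`panel_genes` must contain exactly 100 gene symbols")
  }
  counts <- round(category_proportions * n_chemicals)
  counts[3] <- n_chemicals - sum(counts[1:2])
  cfg <- list(
    seed = as.integer(seed),
    n_fields_per_well = as.integer(n_fields_per_well),
    image_size = as.integer(image_size),
    n_nuclei_per_field = n_nuclei_per_field,
    nucleus_radius_px = nucleus_radius_px,
    foci_per_nucleus = foci_per_nucleus,
    focus_radius_px = focus_radius_px,
    focus_amplitude = focus_amplitude,
    mbd_background = mbd_background,
    nucleus_amplitude = nucleus_amplitude,
    background_noise_sd = background_noise_sd,
    seeding_cv = seeding_cv,
    effect_multipliers = effect_multipliers,
    n_chemicals = as.integer(n_chemicals),
    category_proportions = category_proportions,
    category_counts = stats::setNames(as.integer(counts), c("A", "B", "C")),
    screen_noise_sd = screen_noise_sd,
    n_with_records = as.integer(n_with_records),
    n_activities = as.integer(n_activities),
    n_probes = as.integer(n_probes),
    island_fraction = island_fraction,
    beta_effect = beta_effect,
    beta_noise_sd = beta_noise_sd,
    rrbs_n_sites = as.integer(rrbs_n_sites),
    rrbs_mean_coverage = rrbs_mean_coverage,
    rrbs_dispersion = rrbs_dispersion,
    panel_genes = panel_genes,
    rpkm_noise_sd = rpkm_noise_sd
  )
  structure(cfg, class = "igem_sim_config")
}

#' Default per-chemical effect multipliers for the image generator
#'
#' Multipliers act on (foci intensity, foci area, foci count, nuclei count).
#' `etoposide` carries the hypermethylation-agent profile (1.37, 1.35, 1.34)
#' and `aza_dc` the hypomethylation profile (0.56, 0.56, 0.63).
#'
#' @return A tibble with one row per named treatment.
#' @export
default_effect_multipliers <- function() {
  tibble::tribble(
    ~chemical_id, ~foci_intensity, ~foci_area, ~foci_count, ~nuclei,
    "control",     1.00, 1.00, 1.00, 1.00,
    "etoposide",   1.37, 1.35, 1.34, 0.90,
    "aza_dc",      0.56, 0.56, 0.63, 1.15
  )
}

#' The 100-gene stemness expression panel
#'
#' Gene symbols used for the targeted expression table and the promoter
#' methylation funnel. The first nine entries are the genes whose promoter
#' methylation responds to both hypermethylation agents in the simulated
#' ground truth (NOTCH4, JAG1, LIFR, CCNA2, CCND2, RB1, SMAD4, JUND, CREBBP).
#'
#' @return Character vector of length 100.
#' @export
stem_panel_genes <- function() {
  c(
    "NOTCH4", "JAG1", "LIFR", "CCNA2", "CCND2", "RB1", "SMAD4", "JUND",
    "CREBBP", "POU5F1", "NANOG", "SOX2", "LIN28A", "KLF4", "MYC", "DNMT3B",
    "ZFP42", "SALL4", "DPPA4", "TDGF1", "FGF4", "GDF3", "LEFTY1", "LEFTY2",
    "NODAL", "FOXD3", "TERT", "UTF1", "PRDM14", "ESRRB", "TBX3", "STAT3",
    "SMAD1", "SMAD2", "SMAD3", "BMP4", "FGF2", "WNT3", "WNT5A", "CTNNB1",
    "GSK3B", "AXIN1", "NOTCH1", "NOTCH2", "HES1", "DLL1", "DLL3", "DTX1",
    "LIF", "IL6ST", "CDH1", "CDH2", "EPCAM", "THY1", "PODXL", "ALPL",
    "CD9", "ITGA6", "ITGB1", "FUT4", "KIT", "PAX6", "SOX17", "FOXA2",
    "GATA4", "GATA6", "HAND1", "T", "MIXL1", "EOMES", "GSC", "CER1",
    "AFP", "NES", "TUBB3", "MAP2", "NEUROD1", "OLIG2", "ISL1", "NKX2-5",
    "MYH6", "TNNT2", "ACTC1", "COL1A1", "RUNX1", "RUNX2", "SPP1", "BGLAP",
    "PPARG", "FABP4", "ALB", "TTR", "CDX2", "HNF4A", "HHEX", "SOX7",
    "TP53", "CDKN1A", "CDKN2A", "MDM2"
  )
}

#' @export
print.igem_sim_config <- function(x, ...) {
  cat("<igem_sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  screen:", x$n_chemicals, "chemicals, categories",
      paste(names(x$category_counts), x$category_counts,
            sep = "=", collapse = " "), "\n")
  cat("  imaging:", x$n_fields_per_well, "fields/well,",
      paste(x$image_size, collapse = "x"), "px,",
      x$n_nuclei_per_field, "nuclei/field\n")
  cat("  methylome:", x$n_probes, "probes,", x$rrbs_n_sites, "RRBS sites\n")
  invisible(x)
}

# per-generator seed offsets (stable; never reorder)
.gen_offsets <- c(
  categories = 11L, screen = 23L, activity = 37L, images = 53L,
  beta = 71L, rrbs = 89L, expression = 107L
)
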