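# Synthetic screen table and toxicology-database snapshots with ground truth.

# Latent category profile means on the four ratio parameters
# (foci_intensity, foci_area, foci_count, nuclei).  A: hypomethylation
# (foci down, nuclei up); B: hypermethylation (foci up, nuclei down);
# C: intermediate agents carry a small but reproducible signature
# (intensity up / area down) orthogonal, after centering, to the A/B axis --
# a truly null profile has no shape under a correlation distance and could
# not be clustered at all (see the methods vignette).
.category_means <- list(
  A = c(foci_intensity = 0.70, foci_area = 0.70, foci_count = 0.72, nuclei = 1.15),
  B = c(foci_intensity = 1.30, foci_area = 1.30, foci_count = 1.25, nuclei = 0.85),
  C = c(foci_intensity = 1.06, foci_area = 0.94, foci_count = 1.00, nuclei = 1.00)
)

#' Ground-truth chemical roster with latent methylation categories
#'
#' Deterministically (given the seed) assigns each of the `n_chemicals`
#' chemicals one latent category A (hypomethylation), B (hypermethylation)
#' or C (intermediate), with exact per-category counts taken from
#' `cfg$category_counts` (63/36/36 by default).
#'
#' @param cfg An [sim_config()] object.
#' @return Tibble with columns `chemical_id`, `category`.
#' @export
sim_true_categories <- function(cfg) {
  stopifnot(inherits(cfg, "igem_sim_config"))
  with_gen_seed(cfg$seed, .gen_offsets[["categories"]], code = {
    ids <- sprintf("chem_%03d", seq_len(cfg$n_chemicals))
    cats <- rep(c("A", "B", "C"), times = cfg$category_counts)
    tibble::tibble(
      chemical_id = ids,
      category = sample(cats, length(cats))
    )
  })
}

#' Simulate the chemicals-by-parameters screening ratio table
#'
#' Draws, for every chemical, ratios to the vehicle control of the four
#' fluorescent MBD parameters from its latent category's mean profile plus
#' independent Gaussian noise.
#'
#' @param cfg An [sim_config()] object.
#' @return List with `table` (tibble: `chemical_id`, `foci_intensity`,
#'   `foci_area`, `foci_count`, `nuclei`) and `truth`
#'   (from [sim_true_categories()]).
#' @export
#' @examples
#' sim <- sim_screen_table(sim_config(seed = 7))
#' dplyr::count(sim$truth, category)
sim_screen_table <- function(cfg) {
  stopifnot(inherits(cfg, "igem_sim_config"))
  truth <- sim_true_categories(cfg)
  tab <- with_gen_seed(cfg$seed, .gen_offsets[["screen"]], code = {
    ratios <- purrr::map(truth$category, function(cat) {
      mu <- .category_means[[cat]]
      pmax(mu + stats::rnorm(4, 0, cfg$screen_noise_sd), 1e-6)
    })
    mat <- do.call(rbind, ratios)
    colnames(mat) <- names(.category_means$A)
    dplyr::bind_cols(truth["chemical_id"], tibble::as_tibble(mat))
  })
  list(table = tab, truth = truth)
}

# -- toxicology database snapshots -------------------------------------------

tox21_activity_names <- function(n_extra) {
  base <- c(
    "ER agonist", "ER antagonist", "AR agonist", "AR antagonist",
    "PPARg agonist", "PPARg antagonist", "PPARd agonist", "GR agonist",
    "GR antagonist", "TR agonist", "TR antagonist", "RXR agonist",
    "FXR agonist", "FXR antagonist", "VDR agonist", "VDR antagonist",
    "PXR agonist", "CAR agonist", "AhR agonist", "RORg antagonist",
    "p53 activation", "ARE-Nrf2 activation", "HSE activation",
    "ATAD5 induction", "Aromatase inhibition", "SHH antagonist",
    "Wnt agonist", "Wnt antagonist", "NFkB agonist", "NFkB antagonist",
    "Mitochondrial toxicity", "AP-1 activation", "ESRE activation",
    "TGFb antagonist", "HDAC inhibition", "DNMT inhibition",
    "TSHR agonist", "TSHR antagonist", "ERR agonist", "ERR antagonist",
    "PR agonist", "PR antagonist", "CASP3 activation", "ATXN2 reduction",
    "APP reduction", "Mitotic arrest", "PI3K inhibition", "MAPK inhibition"
  )
  base[seq_len(n_extra)]
}

# Sample Tox21 parent/hydrochloride outcome pairs consistent with a chosen
# harmonised label, so the ground truth exists by construction.
.tox21_pairs <- list(
  active = list(c("active", "active"), c("active", "inconclusive"),
                c("active", "none")),
  inconclusive = list(c("inconclusive", "inconclusive"),
                      c("active", "inactive"), c("inconclusive", "none")),
  inactive = list(c("inactive", "inactive"), c("inactive", "inconclusive"),
                  c("inactive", "none")),
  missing = list(c("none", "none"))
)

#' Simulate GENE-TOX / CCRIS / IARC / Tox21 database snapshots
#'
#' Builds record-level snapshots of the four toxicology sources together with
#' the harmonised ground-truth label of every chemical x activity cell,
#' constructed first and then realised as records guaranteed to map back to
#' it.  Exactly `cfg$n_with_records` chemicals (114 by default) receive
#' records; the rest are absent from every table.  The "CAR antagonist" and
#' "H2AX phosphorylation" activities are enriched for `active` labels among
#' category-B (hypermethylation) chemicals so that the downstream importance
#' ranking has a planted signal to recover.
#'
#' @param cfg An [sim_config()] object.
#' @param categories Optional tibble from [sim_true_categories()]; defaults
#'   to the roster implied by `cfg` (identical stream, so it always lines up
#'   with [sim_screen_table()]).
#' @return List with `genetox`, `ccris`, `iarc`, `tox21` record tibbles, the
#'   chemical `registry`, and `truth` (tibble: `chemical_id`, `activity`,
#'   `label`, plus attribute `labeled_ids`).
#' @export
sim_activity_db <- function(cfg, categories = NULL) {
  stopifnot(inherits(cfg, "igem_sim_config"))
  if (is.null(categories)) categories <- sim_true_categories(cfg)
  acts <- c("genotoxicity", "carcinogenicity", "CAR antagonist",
            "H2AX phosphorylation", tox21_activity_names(cfg$n_activities - 4L))
  with_gen_seed(cfg$seed, .gen_offsets[["activity"]], code = {
    labeled <- sort(sample(categories$chemical_id, cfg$n_with_records))
    genetox <- list(); ccris <- list(); iarc <- list(); tox21 <- list()
    truth <- list()
    for (chem in categories$chemical_id) {
      if (!chem %in% labeled) next
      cat_b <- categories$category[categories$chemical_id == chem] == "B"

      # genotoxicity via GENE-TOX records
      g_lab <- sample(c("active", "inactive", "missing"), 1,
                      prob = c(0.45, 0.45, 0.10))
      if (g_lab != "missing") {
        n_rec <- sample(1:4, 1)
        out <- rep("negative", n_rec)
        if (g_lab == "active") out[sample(n_rec, 1)] <- "positive"
        genetox[[chem]] <- tibble::tibble(
          chemical_id = chem,
          assay_id = sprintf("GT-%02d", seq_len(n_rec)),
          outcome = out
        )
      }
      truth[[paste(chem, "genotoxicity")]] <- g_lab

      # carcinogenicity via IARC group + CCRIS animal records
      c_lab <- sample(c("active", "inconclusive", "inactive", "missing"), 1,
                      prob = c(0.3, 0.25, 0.35, 0.10))
      grp <- "none"; cc_out <- character(0)
      if (c_lab == "active") {
        mode <- sample(3, 1)
        if (mode == 1) {
          grp <- sample(c("1", "2A"), 1)
          if (stats::runif(1) < 0.5) cc_out <- sample(c("positive", "negative"),
                                                      sample(1:3, 1), replace = TRUE)
        } else if (mode == 2) {
          grp <- sample(c("2B", "3"), 1)
          cc_out <- c("positive", sample(c("positive", "negative"),
                                         sample(0:2, 1), replace = TRUE))
        } else {
          grp <- sample(c("4", "none"), 1)
          cc_out <- c("positive", sample(c("positive", "negative"),
                                         sample(0:2, 1), replace = TRUE))
        }
      } else if (c_lab == "inconclusive") {
        grp <- sample(c("2B", "3"), 1)
        cc_out <- rep("negative", sample(0:3, 1))
      } else if (c_lab == "inactive") {
        grp <- sample(c("4", "none"), 1)
        cc_out <- rep("negative", sample(1:3, 1))
      }
      if (grp != "none") {
        iarc[[chem]] <- tibble::tibble(chemical_id = chem, group = grp)
      }
      if (length(cc_out)) {
        ccris[[chem]] <- tibble::tibble(
          chemical_id = chem,
          experiment_id = sprintf("CC-%02d", seq_along(cc_out)),
          outcome = sample(cc_out)
        )
      }
      truth[[paste(chem, "carcinogenicity")]] <- c_lab

      # Tox21 activities via parent/hydrochloride outcome pairs
      for (act in acts[-(1:2)]) {
        planted <- act %in% c("CAR antagonist", "H2AX phosphorylation")
        p_active <- if (planted && cat_b) 0.75 else if (planted) 0.12 else 0.25
        t_lab <- sample(c("active", "inconclusive", "inactive", "missing"), 1,
                        prob = c(p_active, 0.15, 0.85 - p_active, 0.15) /
                          sum(c(p_active, 0.15, 0.85 - p_active, 0.15)))
        pair <- .tox21_pairs[[t_lab]][[sample(length(.tox21_pairs[[t_lab]]), 1)]]
        if (stats::runif(1) < 0.5) pair <- rev(pair)
        tox21[[paste(chem, act)]] <- tibble::tibble(
          chemical_id = chem,
          activity = act,
          form = c("parent", "hydrochloride"),
          outcome = pair
        )
        truth[[paste(chem, act)]] <- t_lab
      }
    }
    truth_tbl <- tibble::tibble(
      chemical_id = rep(labeled, each = length(acts)),
      activity = rep(acts, times = length(labeled)),
      label = unlist(truth[paste(rep(labeled, each = length(acts)),
                                 rep(acts, times = length(labeled)))],
                     use.names = FALSE)
    )
    attr(truth_tbl, "labeled_ids") <- labeled
    list(
      genetox = dplyr::bind_rows(genetox),
      ccris = dplyr::bind_rows(ccris),
      iarc = dplyr::bind_rows(iarc),
      tox21 = dplyr::bind_rows(tox21),
      registry = categories["chemical_id"],
      truth = truth_tbl
    )
  })
}
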