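# End-to-end pipeline driver: stage ordering, configuration, logging and
# report assembly over the synthetic study.

pipeline_stages <- c("simulate", "foci", "screen", "labels", "assoc",
                     "methylome", "rrbs", "expr", "report")

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Unknown keys are rejected.  A resolved copy is written next to the
#' outputs on every run.
#'
#' @param seed Master seed (drives the generators and the forest).
#' @param out_dir Output directory.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param n_imaging_wells Wells per imaging arm in the `foci` stage.
#' @param viability_min Viability gate on the nuclei ratio.
#' @param k Clusters cut for category calling.
#' @param delta Category band half-width.
#' @param eps Beta floor for log2 ratios.
#' @param sigma_beta DiffScore noise model sd.
#' @param diffscore_threshold DiffScore call threshold.
#' @param fold_threshold Beta fold-change threshold for the common
#'   hypermethylated gene set.
#' @param min_effect Funnel threshold on mean log2 methylation ratio
#'   (array data).
#' @param rrbs_min_effect Confirmation threshold on the RRBS mean log2
#'   methylation ratio (coarser counts, so a larger margin than the array
#'   threshold).
#' @param rrbs_min_coverage,rrbs_percentile RRBS coverage filter bounds.
#' @param tile_window RRBS tiling window (bases).
#' @param n_trees Random-forest size.
#' @return A list of class `igem_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("igem_run_"),
                            sim = list(), n_imaging_wells = 2L,
                            viability_min = 0.7, k = 3L, delta = 0.05,
                            eps = 1e-3, sigma_beta = 0.03,
                            diffscore_threshold = -10 * log10(0.05),
                            fold_threshold = 10,
                            min_effect = 0.1, rrbs_min_effect = 0.3,
                            rrbs_min_coverage = 10,
                            rrbs_percentile = 0.999, tile_window = 1000,
                            n_trees = 500L) {
  allowed_sim <- names(formals(sim_config))
  bad <- setdiff(names(sim), allowed_sim)
  if (length(bad)) {
    stop_config(paste("unknown sim config keys:", paste(bad, collapse = ", ")))
  }
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
         n_imaging_wells = as.integer(n_imaging_wells),
         viability_min = viability_min, k = as.integer(k), delta = delta,
         eps = eps, sigma_beta = sigma_beta,
         diffscore_threshold = diffscore_threshold,
         fold_threshold = fold_threshold, min_effect = min_effect,
         rrbs_min_effect = rrbs_min_effect,
         rrbs_min_coverage = rrbs_min_coverage,
         rrbs_percentile = rrbs_percentile, tile_window = tile_window,
         n_trees = as.integer(n_trees)),
    class = "igem_pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg An `igem_pipeline_config`.
#' @return `read_pipeline_config()` returns the validated config;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) {
    stop_config(paste("unknown config keys:", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the synthetic screening pipeline end to end
#'
#' Executes the requested stages in dependency order (`simulate`, `foci`,
#' `screen`, `labels`, `assoc`, `methylome`, `rrbs`, `expr`, `report`),
#' writing each stage's tables as CSV under `cfg$out_dir` together with a
#' resolved copy of the configuration and a plain-text log of every
#' threshold applied.  Stages are deterministic given the configuration,
#' so a rerun reproduces identical outputs.
#'
#' @param cfg An [pipeline_config()] object.
#' @param stages Character subset of stages to run (in any order; they are
#'   sorted into dependency order).  Later stages require earlier ones in
#'   the same call.
#' @return Invisibly, a list with the in-memory results of each stage run
#'   (the `report` element collates the headline numbers).
#' @export
run_pipeline <- function(cfg = pipeline_config(), stages = pipeline_stages) {
  stopifnot(inherits(cfg, "igem_pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) {
    stop_input(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(cfg, file.path(cfg$out_dir, "config_resolved.yaml"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  res <- list()
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop_input(paste0("stage '", stage, "' needs '", what,
                        "'; run its producing stage first"))
    }
    res[[what]]
  }
  out <- function(name, tbl) {
    readr::write_csv(tbl, file.path(cfg$out_dir, paste0(name, ".csv")))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      res$screen <- sim_screen_table(scfg)
      res$db <- sim_activity_db(scfg, res$screen$truth)
      res$beta <- sim_beta_matrix(scfg)
      res$rrbs <- sim_rrbs_calls(scfg)
      res$expr <- sim_expression(scfg, res$beta$truth)
      out("screen_table", res$screen$table)
      out("screen_truth", res$screen$truth)
      for (nm in c("genetox", "ccris", "iarc", "tox21"))
        out(nm, res$db[[nm]])
      out("registry", res$db$registry)
      out("activity_truth", res$db$truth)
      out("beta_annotation", res$beta$annotation)
      out("expression", res$expr$rpkm)
      note("simulate: ", scfg$n_chemicals, " chemicals, categories ",
           paste(scfg$category_counts, collapse = "/"),
           "; ", scfg$n_probes, " probes; seed ", cfg$seed)
    } else if (stage == "foci") {
      chems <- scfg$effect_multipliers$chemical_id
      wells <- purrr::map(chems, function(ch) {
        purrr::map(seq_len(cfg$n_imaging_wells), function(w) {
          quantify_well(sim_plate_images(scfg, ch, well = w),
                        well_id = paste0(ch, "_", w))
        }) |> purrr::list_rbind() |>
          dplyr::mutate(chemical_id = ch)
      }) |> purrr::list_rbind()
      res$well_measures <- wells
      ctrl <- dplyr::filter(wells, .data$chemical_id == "control")
      res$imaging_ratios <- purrr::map(
        setdiff(chems, "control"),
        function(ch) {
          ratio_to_control(dplyr::filter(wells, .data$chemical_id == ch),
                           ctrl) |>
            dplyr::mutate(chemical_id = ch)
        }
      ) |> purrr::list_rbind()
      out("well_measures", wells)
      out("imaging_ratios", res$imaging_ratios)
      note("foci: ", cfg$n_imaging_wells, " wells x ",
           scfg$n_fields_per_well, " fields per arm")
    } else if (stage == "screen") {
      tab <- need("screen", stage)$table
      gated <- viability_gate(tab, cfg$viability_min)
      clust <- cluster_chemicals(gated, k = cfg$k)
      res$categories <- assign_categories(clust, delta = cfg$delta)
      res$clustering <- clust
      out("categories", res$categories)
      cluster_newick(clust, file.path(cfg$out_dir, "dendrogram.nwk"))
      note("screen: viability gate >= ", cfg$viability_min,
           "; k = ", cfg$k, "; delta = ", cfg$delta)
    } else if (stage == "labels") {
      db <- need("db", stage)
      res$labels <- build_activity_matrix(db$genetox, db$ccris, db$iarc,
                                          db$tox21, db$registry)
      out("labels", tibble::as_tibble(res$labels))
      note("labels: ", attr(res$labels, "n_labeled"),
           " chemicals with database records")
    } else if (stage == "assoc") {
      labels <- need("labels", stage)
      tab <- need("screen", stage)$table
      feats <- encode_activities(labels)
      res$importance <- purrr::map(
        stats::setNames(ratio_params, ratio_params),
        function(par) {
          rf_importance(feats, tab[c("chemical_id", par)], par,
                        n_trees = cfg$n_trees, seed = cfg$seed)
        }
      )
      for (par in ratio_params) {
        out(paste0("importance_", par),
            tibble::as_tibble(res$importance[[par]]))
      }
      note("assoc: ", cfg$n_trees, " trees, seed ", cfg$seed)
    } else if (stage == "methylome") {
      bm <- need("beta", stage)
      treatments <- setdiff(names(bm$beta), c("probe_id", "control"))
      calls <- purrr::map(stats::setNames(treatments, treatments),
        function(tr) {
          ds <- diff_score(bm$beta[[tr]], bm$beta$control,
                           sigma_beta = cfg$sigma_beta,
                           threshold = cfg$diffscore_threshold)
          dplyr::bind_cols(bm$beta["probe_id"], ds)
        })
      res$diff_calls <- calls
      res$global_meth <- purrr::imap(calls, function(d, tr) {
        tibble::tibble(
          treatment = tr,
          mean_log2_ratio = beta_log2_summary(bm$beta[[tr]],
                                              bm$beta$control,
                                              cfg$eps)$mean,
          n_called_hyper = sum(d$hypermethylated)
        )
      }) |> purrr::list_rbind()
      res$region <- purrr::imap(
        calls,
        function(d, tr) {
          rd <- region_distribution(d[d$hypermethylated, ], bm$annotation)
          dplyr::bind_rows(
            dplyr::mutate(rd$cpg_context, axis = "cpg_context",
                          level = .data$cpg_context, treatment = tr),
            dplyr::mutate(rd$refgene_group, axis = "refgene_group",
                          level = .data$refgene_group, treatment = tr)
          ) |> dplyr::select("treatment", "axis", "level", "count",
                             "proportion")
        }) |> purrr::list_rbind()
      res$panel_meth <- purrr::map(
        stats::setNames(c("etoposide", "propyl_gallate"),
                        c("etoposide", "propyl_gallate")),
        function(tr) gene_panel_methylation(bm$beta, bm$annotation,
                                            scfg$panel_genes, tr, "control",
                                            cfg$eps)
      )
      res$common_hyper <- {
        fc_calls <- purrr::imap(calls[c("etoposide", "propyl_gallate")],
          function(d, tr) {
            called <- dplyr::filter(d, .data$hypermethylated)
            ann <- dplyr::inner_join(called, bm$annotation, by = "probe_id")
            bt <- bm$beta[[tr]][match(ann$probe_id, bm$beta$probe_id)]
            bc <- bm$beta$control[match(ann$probe_id, bm$beta$probe_id)]
            dplyr::mutate(ann,
                          fold_change = pmax(bt, cfg$eps) / pmax(bc, cfg$eps))
          })
        common_hyper_genes(fc_calls$etoposide, fc_calls$propyl_gallate,
                           cfg$fold_threshold)
      }
      res$tsne <- {
        prof <- vapply(treatments, function(tr)
          beta_log2_summary(bm$beta[[tr]], bm$beta$control,
                            cfg$eps)$log2_ratio,
          numeric(nrow(bm$beta)))
        tsne_embed(t(prof), seed = cfg$seed)
      }
      out("methylome_global", res$global_meth)
      out("region_distribution", res$region)
      out("tsne_beta", res$tsne)
      out("common_hyper_genes",
          tibble::tibble(gene = res$common_hyper))
      note("methylome: DiffScore > ", cfg$diffscore_threshold,
           " (sigma_beta ", cfg$sigma_beta, "); fold threshold > ",
           cfg$fold_threshold)
    } else if (stage == "rrbs") {
      rr <- need("rrbs", stage)
      norm <- rrbs_normalize_coverage(rr$calls)
      filt <- purrr::map(norm, rrbs_filter,
                         min_coverage = cfg$rrbs_min_coverage,
                         percentile = cfg$rrbs_percentile)
      res$rrbs_filtered <- filt
      res$rrbs_tiles <- purrr::map(filt, rrbs_tile,
                                   window = cfg$tile_window)
      res$rrbs_global <- purrr::imap(
        filt[setdiff(names(filt), "control")],
        function(calls, tr) {
          dplyr::mutate(rrbs_global_summary(calls, filt$control, cfg$eps),
                        treatment = tr)
        }) |> purrr::list_rbind()
      res$rrbs_genes <- purrr::imap(
        filt[c("etoposide", "propyl_gallate")],
        function(calls, tr) {
          dplyr::mutate(
            rrbs_gene_methylation(calls, filt$control, rr$gene_map,
                                  cfg$eps),
            treatment = tr)
        }) |> purrr::list_rbind()
      res$rrbs_confirmed <- res$rrbs_genes |>
        dplyr::filter(.data$log2_rate_ratio > cfg$rrbs_min_effect) |>
        dplyr::count(.data$gene) |>
        dplyr::filter(.data$n == 2) |>
        dplyr::pull(.data$gene) |>
        sort()
      out("rrbs_global", res$rrbs_global)
      out("rrbs_gene_methylation", res$rrbs_genes)
      note("rrbs: coverage >= ", cfg$rrbs_min_coverage, ", <= ",
           cfg$rrbs_percentile * 100, "th percentile; window ",
           cfg$tile_window, " b")
    } else if (stage == "expr") {
      ex <- need("expr", stage)
      res$expression <- expression_analysis(ex$rpkm)
      pm <- need("panel_meth", stage)
      res$funnel <- methylation_expression_funnel(
        res$expression$common_down, pm$etoposide, pm$propyl_gallate,
        cfg$min_effect)
      out("fold_change", res$expression$fold_change)
      out("common_down", tibble::tibble(gene = res$expression$common_down))
      note("expr: ", length(res$expression$common_down),
           " commonly decreased genes; funnel ",
           res$funnel$n_down, "/", res$funnel$n_meth_either, "/",
           res$funnel$n_meth_both, " (threshold ", cfg$min_effect, ")")
    } else if (stage == "report") {
      cats <- need("categories", stage)
      report <- list(
        category_counts = as.list(table(cats$category)),
        n_labeled = attr(need("labels", stage), "n_labeled"),
        top_activities = purrr::map(
          need("importance", stage),
          function(im) utils::head(im$activity, 5)),
        global_methylation = need("global_meth", stage),
        funnel = need("funnel", stage)[c("n_down", "n_meth_either",
                                         "n_meth_both")],
        rrbs_confirmed = need("rrbs_confirmed", stage)
      )
      res$report <- report
      yaml::write_yaml(
        purrr::map(report, function(x) {
          if (is.data.frame(x)) purrr::map(x, identity) else x
        }),
        file.path(cfg$out_dir, "report.yaml"))
      note("report: categories ",
           paste(names(report$category_counts),
                 unlist(report$category_counts),
                 sep = "=", collapse = " "))
    }
  }
  writeLines(log_lines, file.path(cfg$out_dir, "pipeline_log.txt"))
  invisible(res)
}
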