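# Targeted panel expression: fold changes, treatment clustering and the
# commonly down-regulated gene set.

#' Fold changes, clustering and common-down genes for the expression panel
#'
#' Fold change is RPKM(treated) / RPKM(control) per gene.  Genes whose
#' control RPKM is zero cannot be normalised; they are flagged and dropped
#' from the fold-change table and clustering.  Treatments are clustered on
#' their gene-wise fold-change profiles with Euclidean distance and
#' average linkage.  The common-down set contains the genes with fold
#' change strictly below 1 under both `down_treatments`.
#'
#' @param rpkm Expression tibble (`gene` + one RPKM column per sample).
#' @param control Name of the vehicle-control column.
#' @param down_treatments Length-2 character vector naming the treatments
#'   whose commonly decreased genes are reported.
#' @return List with `fold_change` (tibble: `gene` + treatment columns),
#'   `hclust` (treatments), `common_down` (gene vector) and
#'   `zero_control_genes`.
#' @export
expression_analysis <- function(rpkm, control = "control",
                                down_treatments = c("etoposide",
                                                    "propyl_gallate")) {
  if (!control %in% names(rpkm)) {
    stop_input(paste0("control column '", control, "' not found"))
  }
  treatments <- setdiff(names(rpkm), c("gene", control))
  if (any(rpkm[[control]] < 0) ||
      any(as.matrix(rpkm[treatments]) < 0)) {
    stop_input("RPKM values must be non-negative")
  }
  zero <- rpkm$gene[rpkm[[control]] == 0]
  keep <- rpkm[rpkm[[control]] > 0, , drop = FALSE]
  fc <- dplyr::bind_cols(
    keep["gene"],
    purrr::map(stats::setNames(treatments, treatments),
               function(tr) keep[[tr]] / keep[[control]]) |>
      tibble::as_tibble()
  )
  hc <- NULL
  if (length(treatments) >= 2) {
    m <- t(as.matrix(fc[treatments]))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    hc$labels <- treatments
  }
  miss_dt <- setdiff(down_treatments, treatments)
  if (length(miss_dt)) {
    stop_input(paste("down_treatments not in table:",
                     paste(miss_dt, collapse = ", ")))
  }
  down <- fc$gene[fc[[down_treatments[1]]] < 1 & fc[[down_treatments[2]]] < 1]
  list(fold_change = fc, hclust = hc, common_down = sort(down),
       zero_control_genes = zero)
}
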