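# Harmonisation of toxicology-database records into one
# active/inconclusive/inactive/missing label per chemical and activity.

genotox_vocab <- c("positive", "negative")
iarc_vocab <- c("1", "2A", "2B", "3", "4", "none")
tox21_vocab <- c("active", "inconclusive", "inactive", "none")

check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad)) {
    stop_input(paste0("unknown ", what, " token(s): ",
                      paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Genotoxicity label from GENE-TOX experiment records
#'
#' A chemical positive in at least one experiment is `active`; one with
#' records that are all negative is `inactive`; one with no records is
#' `missing`.
#'
#' @param outcomes Character vector of per-experiment outcomes
#'   (`positive`/`negative`) for one chemical.
#' @return One of `"active"`, `"inactive"`, `"missing"`.
#' @export
#' @examples
#' label_genotoxicity(c("positive", "negative"))
#' label_genotoxicity(character(0))
label_genotoxicity <- function(outcomes) {
  check_vocab(outcomes, genotox_vocab, "GENE-TOX outcome")
  if (length(outcomes) == 0) return("missing")
  if (any(outcomes == "positive")) "active" else "inactive"
}

#' Carcinogenicity label from IARC group and CCRIS animal records
#'
#' Decision tree: IARC groups 1 and 2A are `active` outright.  For groups
#' 2B and 3, at least one positive animal experiment gives `active`,
#' otherwise `inconclusive` (including the vacuous case of no animal
#' records -- see the methods vignette).  Group 4 and chemicals without an
#' IARC group are `active` with at least one positive record, `inactive`
#' with records that are all negative, and `missing` with neither group
#' nor records.
#'
#' @param group IARC group token: `"1"`, `"2A"`, `"2B"`, `"3"`, `"4"` or
#'   `"none"`.
#' @param ccris Character vector of CCRIS animal-experiment outcomes
#'   (`positive`/`negative`).
#' @return One of `"active"`, `"inconclusive"`, `"inactive"`, `"missing"`.
#' @export
label_carcinogenicity <- function(group, ccris = character(0)) {
  check_vocab(group, iarc_vocab, "IARC group")
  check_vocab(ccris, genotox_vocab, "CCRIS outcome")
  if (length(group) != 1) stop_input("`group` must be a single token")
  if (group %in% c("1", "2A")) return("active")
  if (group %in% c("2B", "3")) {
    return(if (any(ccris == "positive")) "active" else "inconclusive")
  }
  # group 4 or no IARC data
  if (length(ccris) == 0) return("missing")
  if (any(ccris == "positive")) "active" else "inactive"
}

#' Merge Tox21 outcomes of a parent compound and its hydrochloride
#'
#' Symmetric merge rule: `{active, inconclusive} -> active`,
#' `{active, inactive} -> inconclusive`, `{inactive, inconclusive} ->
#' inactive`; equal outcomes keep their value; a `none` side defers to the
#' other; two `none` give `missing`.  (The `{active, inactive} ->
#' inconclusive` case follows the harmonisation rule as stated for the
#' source databases; see the methods vignette for discussion.)
#'
#' @param parent,hydrochloride Tox21 outcome tokens
#'   (`active`/`inconclusive`/`inactive`/`none`).
#' @return One of `"active"`, `"inconclusive"`, `"inactive"`, `"missing"`.
#' @export
#' @examples
#' merge_tox21("active", "inconclusive")
#' merge_tox21("active", "inactive")
merge_tox21 <- function(parent, hydrochloride) {
  check_vocab(c(parent, hydrochloride), tox21_vocab, "Tox21 outcome")
  a <- parent; b <- hydrochloride
  if (a == "none" && b == "none") return("missing")
  if (a == "none") return(b)
  if (b == "none") return(a)
  if (a == b) return(a)
  s <- sort(c(a, b))
  if (identical(s, c("active", "inconclusive"))) return("active")
  if (identical(s, c("active", "inactive"))) return("inconclusive")
  if (identical(s, c("inactive", "inconclusive"))) return("inactive")
  stop_input("unreachable Tox21 combination")  # nocov
}

#' Build the chemicals-by-activities label matrix from database snapshots
#'
#' Applies [label_genotoxicity()], [label_carcinogenicity()] and
#' [merge_tox21()] per chemical and activity, then drops chemicals that are
#' `missing` in every column (no records in any database).
#'
#' @param genetox Tibble: `chemical_id`, `assay_id`, `outcome`.
#' @param ccris Tibble: `chemical_id`, `experiment_id`, `outcome`.
#' @param iarc Tibble: `chemical_id`, `group` (one row per chemical).
#' @param tox21 Tibble: `chemical_id`, `activity`, `form`
#'   (`parent`/`hydrochloride`), `outcome`.
#' @param registry Tibble with a `chemical_id` column enumerating all
#'   screened chemicals (the join key across databases).
#' @return Long tibble of class `igem_activity_matrix`: `chemical_id`,
#'   `activity`, `label`; attribute `n_labeled` records the labelled-subset
#'   size.
#' @export
build_activity_matrix <- function(genetox, ccris, iarc, tox21, registry) {
  if (!"chemical_id" %in% names(registry)) {
    stop_input("`registry` must have a `chemical_id` column")
  }
  chems <- unique(registry$chemical_id)
  tox21_acts <- if (nrow(tox21)) sort(unique(tox21$activity)) else character(0)

  per_chem <- purrr::map(chems, function(ch) {
    g <- genetox$outcome[genetox$chemical_id == ch]
    cc <- ccris$outcome[ccris$chemical_id == ch]
    grp <- iarc$group[iarc$chemical_id == ch]
    if (length(grp) > 1) {
      stop_input(paste0("multiple IARC groups for ", ch))
    }
    if (length(grp) == 0) grp <- "none"
    rows <- list(
      tibble::tibble(chemical_id = ch, activity = "genotoxicity",
                     label = label_genotoxicity(g)),
      tibble::tibble(chemical_id = ch, activity = "carcinogenicity",
                     label = label_carcinogenicity(grp, cc))
    )
    if (length(tox21_acts)) {
      tx <- tox21[tox21$chemical_id == ch, ]
      rows <- c(rows, purrr::map(tox21_acts, function(act) {
        sub <- tx[tx$activity == act, ]
        get1 <- function(form) {
          o <- sub$outcome[sub$form == form]
          if (length(o) == 0) "none" else o[[1]]
        }
        tibble::tibble(chemical_id = ch, activity = act,
                       label = merge_tox21(get1("parent"),
                                           get1("hydrochloride")))
      }))
    }
    dplyr::bind_rows(rows)
  }) |> purrr::list_rbind()

  labeled <- per_chem |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::filter(any(.data$label != "missing")) |>
    dplyr::ungroup()
  structure(labeled,
            n_labeled = dplyr::n_distinct(labeled$chemical_id),
            class = c("igem_activity_matrix", class(labeled)))
}

#' Pivot an activity label matrix to wide form
#'
#' @param matrix Long label tibble from [build_activity_matrix()].
#' @return Wide tibble, chemicals in rows and activities in columns.
#' @export
activity_matrix_wide <- function(matrix) {
  tidyr::pivot_wider(tibble::as_tibble(matrix), names_from = "activity",
                     values_from = "label")
}
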