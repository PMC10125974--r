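# Quantification of nuclei and MBD foci from two-channel field images,
# mirroring the four-step high-content pipeline: nuclear segmentation,
# foci segmentation, and per-well measurement.  Cell segmentation is folded
# into nuclear segmentation because every reported parameter is nuclear.

as_img <- function(m) EBImage::Image(m)
blur <- function(m, sigma) as.matrix(EBImage::gblur(as_img(m), sigma = sigma))

#' Segment nuclei from the blue (Hoechst) channel
#'
#' Gaussian smoothing, Otsu thresholding, hole filling and a
#' distance-transform watershed to split touching nuclei.  Regions outside
#' the area band and nuclei touching the image border are discarded; labels
#' are re-numbered consecutively from 1.
#'
#' @param img Numeric intensity matrix (non-negative).
#' @param min_area_px,max_area_px Retained nucleus area band in pixels.
#' @param smooth_sigma Gaussian sigma (px) applied before thresholding.
#' @return An object of class `igem_nucleus_mask`: list with `label_map`
#'   (integer matrix, 0 = background), `areas` (named integer vector) and
#'   `n` (number of nuclei).
#' @export
segment_nuclei <- function(img, min_area_px = 120, max_area_px = 5000,
                           smooth_sigma = 2) {
  if (!is.matrix(img) || length(img) == 0) {
    stop_input("`img` must be a non-empty numeric matrix")
  }
  if (any(img < 0)) stop_input("intensities must be non-negative")
  rng <- range(img)
  if (diff(rng) == 0) {
    return(new_nucleus_mask(matrix(0L, nrow(img), ncol(img))))
  }
  norm <- (img - rng[1]) / diff(rng)
  sm <- blur(norm, smooth_sigma)
  sm <- pmin(pmax(sm, 0), 1)
  th <- EBImage::otsu(as_img(sm))
  # a blank (noise-only) field still yields an Otsu split of the noise;
  # require real foreground/background contrast before segmenting
  fg <- sm > th
  if (!any(fg) || all(fg) ||
      stats::median(img[fg]) <
        stats::median(img[!fg]) + 5 * robust_sd(img[!fg])) {
    return(new_nucleus_mask(matrix(0L, nrow(img), ncol(img))))
  }
  bw <- EBImage::fillHull(as_img(fg))
  dm <- EBImage::distmap(bw)
  lab <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  lab <- filter_labels(lab, min_area_px, max_area_px)
  new_nucleus_mask(lab)
}

# drop border-touching and out-of-band regions, relabel 1..K
filter_labels <- function(lab, min_area, max_area) {
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(labs)) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    areas <- tabulate(lab[lab > 0], nbins = max(labs))
    keep <- setdiff(labs[areas[labs] >= min_area & areas[labs] <= max_area],
                    border)
    lab[!(lab %in% keep)] <- 0L
    lab[] <- match(lab, c(0L, keep)) - 1L
  }
  lab
}

new_nucleus_mask <- function(label_map) {
  label_map <- matrix(as.integer(label_map), nrow(label_map), ncol(label_map))
  n <- max(label_map)
  areas <- if (n > 0) tabulate(label_map[label_map > 0], nbins = n) else integer(0)
  structure(list(label_map = label_map,
                 areas = stats::setNames(as.integer(areas), seq_len(n)),
                 n = as.integer(n)),
            class = "igem_nucleus_mask")
}

#' @export
print.igem_nucleus_mask <- function(x, ...) {
  cat("<igem_nucleus_mask>", x$n, "nuclei,",
      paste(dim(x$label_map), collapse = "x"), "px\n")
  invisible(x)
}

#' Nucleus centroids of a segmentation mask
#'
#' @param mask An `igem_nucleus_mask`.
#' @return Tibble with `nucleus_label`, `x`, `y` (pixel coordinates) and
#'   `area_px`.
#' @export
nucleus_centroids <- function(mask) {
  stopifnot(inherits(mask, "igem_nucleus_mask"))
  lab <- mask$label_map
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(tibble::tibble(nucleus_label = integer(0), x = numeric(0),
                          y = numeric(0), area_px = integer(0)))
  }
  l <- lab[idx]
  xs <- (idx - 1) %% nrow(lab) + 1
  ys <- (idx - 1) %/% nrow(lab) + 1
  tibble::tibble(
    nucleus_label = sort(unique(l)),
    x = as.numeric(tapply(xs, l, mean)),
    y = as.numeric(tapply(ys, l, mean)),
    area_px = as.integer(tabulate(l, nbins = max(l))[sort(unique(l))])
  )
}

#' Detect MBD foci inside segmented nuclei
#'
#' Two-stage segmentation.  A difference-of-Gaussians band-pass at
#' `spot_sigma_px` (vs 2.5x) seeds candidate spots where the enhanced
#' intensity exceeds the nucleus median plus `k_threshold` robust standard
#' deviations (MAD).  The focus footprint itself is then measured on the raw
#' image -- pixels above the nucleus median plus `k_measure` robust sd --
#' because band-pass filtering broadens spots and would distort the area
#' read-out.  Touching foci are split by an intensity watershed whose
#' tolerance is `split_tolerance` robust sd (all cuts are relative to
#' per-nucleus robust statistics, so detection commutes with rescaling the
#' channel).  Components that never touch a band-pass seed are discarded as
#' noise speckle, as are components smaller than `min_spot_px`.  Intensities
#' are measured on the raw image with the nucleus median as local
#' background, so `integrated_intensity` is background-subtracted.
#'
#' @param img Numeric matrix, red (MBD) channel of the same field.
#' @param mask `igem_nucleus_mask` from the matching blue channel.
#' @param spot_sigma_px Focus scale for the band-pass seed filter (px).
#' @param k_threshold Robust z-score cut for band-pass seeds.
#' @param k_measure Robust z-score cut defining the measured footprint.
#' @param split_tolerance Watershed tolerance in robust-sd units.
#' @param min_spot_px Minimum focus area in pixels.
#' @return Tibble of focus records: `nucleus_label`, `area_px`,
#'   `mean_intensity`, `integrated_intensity`.
#' @export
detect_foci <- function(img, mask, spot_sigma_px = 1.3, k_threshold = 5,
                        k_measure = 2.5, split_tolerance = 2,
                        min_spot_px = 3) {
  stopifnot(inherits(mask, "igem_nucleus_mask"))
  if (!is.matrix(img) || !all(dim(img) == dim(mask$label_map))) {
    stop_input("`img` dimensions must match the nucleus mask")
  }
  empty <- tibble::tibble(nucleus_label = integer(0), area_px = integer(0),
                          mean_intensity = numeric(0),
                          integrated_intensity = numeric(0))
  if (mask$n == 0) return(empty)
  lab <- mask$label_map
  inside <- lab > 0
  dog <- blur(img, spot_sigma_px) - blur(img, 2.5 * spot_sigma_px)

  per_nuc <- function(v, where) {
    s <- split(v[where], lab[where])
    out <- matrix(NA_real_, mask$n, 2, dimnames = list(NULL, c("med", "rsd")))
    idx <- as.integer(names(s))
    out[idx, "med"] <- vapply(s, stats::median, numeric(1))
    out[idx, "rsd"] <- pmax(vapply(s, robust_sd, numeric(1)), 1e-9)
    out
  }
  st_dog <- per_nuc(dog, inside)

  lift <- function(stats_mat, col) {
    out <- matrix(Inf, nrow(lab), ncol(lab))
    out[inside] <- stats_mat[lab[inside], col]
    out
  }
  seed_mask <- dog > lift(st_dog, "med") + k_threshold * lift(st_dog, "rsd")

  # background statistics of the raw channel, excluding a dilated margin
  # around seeded spots so that nuclei with many foci do not get inflated
  # thresholds (which would couple the area read-out to the focus count)
  bg_excl <- as.matrix(EBImage::dilate(as_img(seed_mask),
                                       EBImage::makeBrush(7, "disc"))) > 0
  bg_where <- inside & !bg_excl
  st_raw <- per_nuc(img, bg_where)
  fallback <- is.na(st_raw[, "med"])
  if (any(fallback)) {
    st_all <- per_nuc(img, inside)
    st_raw[fallback, ] <- st_all[fallback, ]
  }
  thr_raw <- lift(st_raw, "med") + k_measure * lift(st_raw, "rsd")
  meas_mask <- img > thr_raw
  if (!any(meas_mask & seed_mask)) return(empty)

  # intensity watershed over the above-threshold relief splits merged foci;
  # a light smoothing of the relief removes single-pixel noise maxima so a
  # small tolerance can be used without over-splitting
  relief <- matrix(0, nrow(lab), ncol(lab))
  relief[meas_mask] <- img[meas_mask] - thr_raw[meas_mask]
  tol <- split_tolerance * stats::median(st_raw[, "rsd"])
  comp <- as.matrix(EBImage::watershed(as_img(relief), tolerance = tol, ext = 1))
  if (max(comp) == 0) return(empty)

  cidx <- which(comp > 0)
  raw_med <- st_raw[, "med"]
  recs <- tibble::tibble(component = comp[cidx], nucleus_label = lab[cidx],
                         raw = img[cidx], seeded = seed_mask[cidx]) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      nucleus_label = as.integer(names(which.max(table(.data$nucleus_label)))),
      area_px = dplyr::n(),
      total_raw = sum(.data$raw),
      seeded = any(.data$seeded),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$seeded, .data$area_px >= min_spot_px) |>
    dplyr::mutate(
      mean_intensity = .data$total_raw / .data$area_px,
      integrated_intensity = .data$total_raw -
        .data$area_px * raw_med[.data$nucleus_label]
    ) |>
    dplyr::select("nucleus_label", "area_px", "mean_intensity",
                  "integrated_intensity") |>
    dplyr::arrange(.data$nucleus_label)
  recs
}

#' Summarise one well from its per-field masks and focus records
#'
#' The three foci parameters are per-nucleus means over the whole well:
#' each is the sum of the per-focus quantity over all foci divided by the
#' total nucleus count, so nuclei without foci dilute the mean (contribute
#' 0 to the numerator, 1 to the denominator).
#'
#' @param fields List of fields, each a list with elements `mask`
#'   (`igem_nucleus_mask`) and `foci` (tibble from [detect_foci()]).
#' @param well_id Identifier copied into the output.
#' @return One-row tibble: `well_id`, `nuclei_count`,
#'   `foci_intensity_per_nucleus`, `foci_area_per_nucleus`,
#'   `foci_count_per_nucleus`, `defined` (FALSE when no nuclei were found,
#'   in which case the per-nucleus parameters are NA).
#' @export
measure_well <- function(fields, well_id = "well") {
  if (length(fields) == 0) stop_input("`fields` must contain at least one field")
  n_nuc <- sum(vapply(fields, function(f) f$mask$n, integer(1)))
  foci <- dplyr::bind_rows(lapply(fields, `[[`, "foci"))
  if (n_nuc == 0) {
    return(tibble::tibble(well_id = well_id, nuclei_count = 0L,
                          foci_intensity_per_nucleus = NA_real_,
                          foci_area_per_nucleus = NA_real_,
                          foci_count_per_nucleus = NA_real_,
                          defined = FALSE))
  }
  tibble::tibble(
    well_id = well_id,
    nuclei_count = as.integer(n_nuc),
    foci_intensity_per_nucleus = sum(foci$integrated_intensity) / n_nuc,
    foci_area_per_nucleus = sum(foci$area_px) / n_nuc,
    foci_count_per_nucleus = nrow(foci) / n_nuc,
    defined = TRUE
  )
}

#' Quantify a simulated or loaded well end to end
#'
#' Convenience wrapper: segments every field's blue channel, detects foci in
#' the red channel, and summarises the well.
#'
#' @param well List with a `fields` element as produced by
#'   [sim_plate_images()] (each field a list of `nuclei` and `mbd`
#'   matrices).
#' @param well_id Identifier for the output row.
#' @param ... Passed to [segment_nuclei()] and [detect_foci()] (matched by
#'   name: `min_area_px`, `max_area_px`, `smooth_sigma`, `spot_sigma_px`,
#'   `k_threshold`, `min_spot_px`).
#' @return One-row tibble as from [measure_well()].
#' @export
quantify_well <- function(well, well_id = "well", ...) {
  dots <- list(...)
  seg_args <- dots[names(dots) %in% c("min_area_px", "max_area_px", "smooth_sigma")]
  foc_args <- dots[names(dots) %in% c("spot_sigma_px", "k_threshold",
                                      "k_measure", "split_tolerance",
                                      "min_spot_px")]
  fields <- lapply(well$fields, function(f) {
    mask <- do.call(segment_nuclei, c(list(f$nuclei), seg_args))
    foci <- do.call(detect_foci, c(list(f$mbd, mask), foc_args))
    list(mask = mask, foci = foci)
  })
  measure_well(fields, well_id = well_id)
}
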