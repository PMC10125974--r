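# Synthetic two-channel field images: Hoechst-stained nuclei (blue) and
# punctate mCherry-MBD foci (red), with per-nucleus ground truth.

# add a Gaussian spot to `mat` in-place-ish over a local window
add_gaussian <- function(mat, cx, cy, sigma, amp) {
  w <- ceiling(4 * sigma)
  xs <- max(1, round(cx) - w):min(nrow(mat), round(cx) + w)
  ys <- max(1, round(cy) - w):min(ncol(mat), round(cy) + w)
  gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
  gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
  mat[xs, ys] <- mat[xs, ys] + amp * outer(gx, gy)
  mat
}

# add a soft-edged disk (logistic edge ~1 px) over a local window
add_disk <- function(mat, cx, cy, r, amp) {
  w <- ceiling(r + 4)
  xs <- max(1, round(cx) - w):min(nrow(mat), round(cx) + w)
  ys <- max(1, round(cy) - w):min(ncol(mat), round(cy) + w)
  d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
  mat[xs, ys] <- mat[xs, ys] + amp / (1 + exp((d - r) / 0.8))
  mat
}

# rejection-sample nucleus centres with a minimum separation
sample_centres <- function(n, size, r_mean, min_sep, max_try = 2000) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  margin <- r_mean + 2
  while (nrow(pts) < n && tries < max_try) {
    cand <- c(stats::runif(1, margin, size[1] - margin),
              stats::runif(1, margin, size[2] - margin))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1
  }
  pts
}

#' Simulate one well's two-channel field images with ground truth
#'
#' Renders `cfg$n_fields_per_well` fields for one treated well. The blue
#' channel holds soft-edged nuclear disks; the red channel holds a diffuse
#' nuclear background plus Gaussian MBD foci. The chemical's effect
#' multipliers scale true per-nucleus foci integrated intensity, foci area
#' (via the spot footprint), foci count (Poisson mean) and the number of
#' nuclei. Both channels receive additive Gaussian noise.
#'
#' @param cfg An [sim_config()] object.
#' @param chemical_id A row of `cfg$effect_multipliers` (e.g. `"control"`,
#'   `"etoposide"`, `"aza_dc"`).
#' @param well Integer well index; different wells of the same chemical get
#'   independent (but seed-reproducible) draws.
#' @return List with `fields` (each a list of `nuclei` and `mbd` intensity
#'   matrices) and `truth`, a tibble with one row per simulated nucleus:
#'   centroid, radius, true foci count, true summed focus footprint area
#'   (pixels), true summed integrated focus intensity, and a `crowded` flag
#'   marking nuclei where any two foci centres lie closer than twice the
#'   focus radius.
#' @export
#' @examples
#' well <- sim_plate_images(sim_config(seed = 1, n_fields_per_well = 2),
#'                          "control")
#' dim(well$fields[[1]]$nuclei)
sim_plate_images <- function(cfg, chemical_id, well = 1L) {
  stopifnot(inherits(cfg, "igem_sim_config"))
  mult <- cfg$effect_multipliers |> dplyr::filter(.data$chemical_id == !!chemical_id)
  if (nrow(mult) != 1) {
    stop_config(paste0("no effect multipliers defined for chemical '",
                       chemical_id, "'"))
  }
  size <- cfg$image_size
  with_gen_seed(cfg$seed, .gen_offsets[["images"]],
                key = paste(chemical_id, well), code = {
    # The multipliers are defined on the measured per-nucleus parameters
    # (count/nucleus, summed area/nucleus, summed intensity/nucleus), so the
    # per-focus knobs must be deflated by the count multiplier: count scales
    # the Poisson mean, per-focus footprint scales by area/count, and
    # per-focus amplitude by intensity/area, making the per-nucleus sums
    # scale by exactly (intensity, area, count).
    mc <- if (mult$foci_count > 0) mult$foci_count else 1
    sigma_f <- cfg$focus_radius_px * sqrt(mult$foci_area / mc)
    amp_f <- cfg$focus_amplitude * mult$foci_intensity / mult$foci_area
    lambda <- cfg$foci_per_nucleus * mult$foci_count
    n_target <- cfg$n_nuclei_per_field * mult$nuclei
    fields <- vector("list", cfg$n_fields_per_well)
    truth <- vector("list", cfg$n_fields_per_well)
    for (f in seq_len(cfg$n_fields_per_well)) {
      n_nuc <- if (cfg$seeding_cv > 0) {
        max(0L, round(stats::rnorm(1, n_target, cfg$seeding_cv * n_target)))
      } else {
        round(n_target)
      }
      blue <- matrix(0, size[1], size[2])
      red <- matrix(0, size[1], size[2])
      ctr <- sample_centres(n_nuc, size, cfg$nucleus_radius_px[1],
                            min_sep = 2.4 * cfg$nucleus_radius_px[1])
      rows <- vector("list", nrow(ctr))
      for (i in seq_len(nrow(ctr))) {
        r <- max(4, stats::rnorm(1, cfg$nucleus_radius_px[1],
                                 cfg$nucleus_radius_px[2]))
        blue <- add_disk(blue, ctr[i, 1], ctr[i, 2], r, cfg$nucleus_amplitude)
        red <- add_disk(red, ctr[i, 1], ctr[i, 2], r, cfg$mbd_background)
        k <- stats::rpois(1, lambda)
        fx <- fy <- numeric(0)
        if (k > 0) {
          # soft repulsion between foci: distinct puncta rarely coincide,
          # so each focus retries a few times to clear its neighbours; on
          # failure it is placed anyway (and the nucleus flagged crowded)
          min_sep <- 3 * cfg$focus_radius_px
          for (j in seq_len(k)) {
            for (try in 1:40) {
              ang <- stats::runif(1, 0, 2 * pi)
              rad <- r * 0.8 * sqrt(stats::runif(1))
              px <- ctr[i, 1] + rad * cos(ang)
              py <- ctr[i, 2] + rad * sin(ang)
              if (!length(fx) ||
                  min(sqrt((fx - px)^2 + (fy - py)^2)) >= min_sep) break
            }
            fx <- c(fx, px); fy <- c(fy, py)
            red <- add_gaussian(red, px, py, sigma_f, amp_f)
          }
        }
        crowded <- k > 1 &&
          min(stats::dist(cbind(fx, fy))) < 2 * cfg$focus_radius_px
        rows[[i]] <- tibble::tibble(
          field = f, nucleus = i, x = ctr[i, 1], y = ctr[i, 2], radius = r,
          n_foci = k,
          foci_area_true = k * pi * (2 * sigma_f)^2,
          foci_intensity_true = k * 2 * pi * sigma_f^2 * amp_f,
          crowded = crowded
        )
      }
      blue <- blue + matrix(stats::rnorm(length(blue), 0, cfg$background_noise_sd),
                            size[1], size[2])
      red <- red + matrix(stats::rnorm(length(red), 0, cfg$background_noise_sd),
                          size[1], size[2])
      fields[[f]] <- list(nuclei = pmax(blue, 0), mbd = pmax(red, 0))
      truth[[f]] <- if (length(rows)) dplyr::bind_rows(rows) else
        tibble::tibble(field = integer(0), nucleus = integer(0), x = numeric(0),
                       y = numeric(0), radius = numeric(0), n_foci = integer(0),
                       foci_area_true = numeric(0),
                       foci_intensity_true = numeric(0), crowded = logical(0))
    }
    list(fields = fields, truth = dplyr::bind_rows(truth))
  })
}

#' Write / read a two-channel field as a multi-page TIFF
#'
#' Page 1 carries the nuclei (blue) channel and page 2 the MBD (red)
#' channel, stored as 32-bit floats in native intensity units.
#'
#' @param field A list with `nuclei` and `mbd` matrices.
#' @param path Output file path.
#' @return `write_field_tiff()` returns `path` invisibly;
#'   `read_field_tiff()` returns a `list(nuclei=, mbd=)`.
#' @export
write_field_tiff <- function(field, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_input("the 'tiff' package is required for TIFF i/o")
  }
  # fixed scale keeps intensities in the writable [0,1] float range while
  # preserving absolute units on round-trip
  scale <- 65536
  tiff::writeTIFF(list(pmin(field$nuclei / scale, 1), pmin(field$mbd / scale, 1)),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_input("the 'tiff' package is required for TIFF i/o")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop_input("expected a two-page TIFF (nuclei, mbd)")
  list(nuclei = pages[[1]] * 65536, mbd = pages[[2]] * 65536)
}
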