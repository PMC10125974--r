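# Shared fixtures: small configs and a manually rendered field with known
# geometry, used across the imaging tests.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_fields_per_well = 2L, ...)
}

# render one field with nuclei at fixed centres and foci at fixed offsets
render_field <- function(centres, n_foci = 3, radius = 16,
                         focus_sigma = 1.0, focus_amp = 600,
                         noise_sd = 10, size = 256, seed = 42,
                         focus_spread = 8) {
  withr::with_seed(seed, {
    blue <- matrix(0, size, size)
    red <- matrix(0, size, size)
    truth <- list()
    for (i in seq_len(nrow(centres))) {
      blue <- igemscreen:::add_disk(blue, centres[i, 1], centres[i, 2],
                                    radius, 400)
      red <- igemscreen:::add_disk(red, centres[i, 1], centres[i, 2],
                                   radius, 60)
      if (n_foci > 0) {
        ang <- seq_len(n_foci) * 2 * pi / n_foci
        fx <- centres[i, 1] + focus_spread * cos(ang)
        fy <- centres[i, 2] + focus_spread * sin(ang)
        for (j in seq_len(n_foci)) {
          red <- igemscreen:::add_gaussian(red, fx[j], fy[j], focus_sigma,
                                           focus_amp)
        }
      }
      truth[[i]] <- tibble::tibble(nucleus = i, x = centres[i, 1],
                                   y = centres[i, 2], n_foci = n_foci)
    }
    blue <- pmax(blue + matrix(rnorm(size^2, 0, noise_sd), size, size), 0)
    red <- pmax(red + matrix(rnorm(size^2, 0, noise_sd), size, size), 0)
    list(nuclei = blue, mbd = red, truth = dplyr::bind_rows(truth))
  })
}

well_separated_centres <- function() {
  rbind(c(60, 60), c(180, 60), c(60, 180), c(180, 180), c(120, 120))
}

# Monte-Carlo joint-permutation oracle for the Steel-Dwass adjusted p:
# permute all observations, recompute every pairwise standardised rank
# statistic, and take the tail probability of the max sqrt(2)|t|.
steel_dwass_perm_oracle <- function(values, group, B = 4000, seed = 99) {
  group <- factor(group)
  pairs <- utils::combn(levels(group), 2)
  stat_all <- function(v) {
    apply(pairs, 2, function(pr) {
      sqrt(2) * abs(igemscreen:::steel_dwass_stat(v[group == pr[1]],
                                                  v[group == pr[2]]))
    })
  }
  obs <- stat_all(values)
  mx <- withr::with_seed(seed,
                         replicate(B, max(stat_all(sample(values)))))
  vapply(obs, function(o) mean(mx >= o - 1e-12), numeric(1))
}
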