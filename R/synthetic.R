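# Synthetic assay data and rendered flask photographs with known ground truth.
#
# The assay model emulates the observed calibration shape: GPI responds
# linearly to chlorophyll up to a breakpoint concentration, then saturates,
# approaching a plateau exponentially with the rate fixed so the curve is C1
# (the slope is continuous at the breakpoint). Photograph-to-photograph
# variability is additive Gaussian noise on GPI; the default noise SD of 0.002
# yields mid-curve replicate precision of roughly 5 %RSD, the scale the
# physical assay shows.

#' Configuration for the synthetic calibration assay
#'
#' Defaults mirror the control condition of the physical assay: slope 0.00694
#' GPI per ug/ml, near-zero intercept, linearity up to 16 ug/ml, triplicate
#' photographs, and GPI noise SD 0.002.
#'
#' @param true_slope Linear-segment slope (GPI per ug/ml), > 0.
#' @param true_intercept Intercept (GPI).
#' @param noise_sd_gpi SD of the additive per-photograph GPI noise (>= 0).
#' @param breakpoint_chl Concentration at which saturation begins (ug/ml).
#' @param plateau_gpi Asymptotic GPI; must exceed the linear value at the
#'   breakpoint.
#' @param conc_grid Concentrations of the calibration samples (ug/ml); the
#'   breakpoint must lie within their range.
#' @param photos_per_sample Photographs per sample (the protocol uses 3).
#' @param n_blanks Number of blank (media-only) replicate measurements.
#' @return A validated list of class `assay_config`.
#' @export
assay_config <- function(true_slope = 0.00694,
                         true_intercept = 0.000799,
                         noise_sd_gpi = 0.002,
                         breakpoint_chl = 16,
                         plateau_gpi = 0.12,
                         conc_grid = seq(0.1, 25, length.out = 25),
                         photos_per_sample = 3L,
                         n_blanks = 10L) {
  if (true_slope <= 0) stop_contract("true_slope must be positive")
  if (noise_sd_gpi < 0) stop_contract("noise_sd_gpi must be non-negative")
  if (breakpoint_chl < min(conc_grid) || breakpoint_chl > max(conc_grid)) {
    stop_contract("breakpoint_chl must lie within the range of conc_grid")
  }
  y_bp <- true_slope * breakpoint_chl + true_intercept
  if (plateau_gpi <= y_bp) {
    stop_contract("plateau_gpi must exceed the linear response at the breakpoint (",
                  signif(y_bp, 4), ")")
  }
  if (!is_count(photos_per_sample) || photos_per_sample < 1) {
    stop_contract("photos_per_sample must be a positive integer")
  }
  if (!is_count(n_blanks) || n_blanks < 3) {
    stop_contract("n_blanks must be an integer >= 3")
  }
  structure(
    list(
      true_slope = true_slope, true_intercept = true_intercept,
      noise_sd_gpi = noise_sd_gpi,
      breakpoint_chl = breakpoint_chl, plateau_gpi = plateau_gpi,
      conc_grid = sort(conc_grid),
      photos_per_sample = as.integer(photos_per_sample),
      n_blanks = as.integer(n_blanks)
    ),
    class = "assay_config"
  )
}

#' Noise-free mean GPI response of the synthetic assay
#'
#' Linear below the breakpoint; beyond it an exponential approach to the
#' plateau with rate `k = slope / (plateau - y_breakpoint)` so that the slope
#' is continuous at the breakpoint.
#'
#' @param chl Concentration(s), ug/ml.
#' @param config An [assay_config()].
#' @return Mean GPI value(s).
#' @export
assay_mean_response <- function(chl, config) {
  stopifnot(inherits(config, "assay_config"))
  y_bp <- config$true_slope * config$breakpoint_chl + config$true_intercept
  k <- config$true_slope / (config$plateau_gpi - y_bp)
  lin <- config$true_slope * chl + config$true_intercept
  sat <- config$plateau_gpi -
    (config$plateau_gpi - y_bp) * exp(-k * (chl - config$breakpoint_chl))
  ifelse(chl <= config$breakpoint_chl, lin, sat)
}

#' Simulate a calibration dataset with known ground truth
#'
#' Draws triplicate per-photograph GPI readings around the assay's mean
#' response at each configured concentration, and blank replicates around the
#' intercept-free zero (blank `gpi_final` is centered at 0 by construction,
#' since the baseline flask is subtracted). Deterministic given `seed`.
#'
#' @param config An [assay_config()].
#' @param seed Integer seed.
#' @return A list with `points` (data frame: `sample_id`, `pigment`, `chl`,
#'   `gpi_final`, `gpi_rep1..3`), `blanks` (numeric vector of blank
#'   `gpi_final` replicates), and `truth` (the config plus the noise-free mean
#'   response at each concentration).
#' @export
simulate_calibration_dataset <- function(config = assay_config(), seed = 1L) {
  stopifnot(inherits(config, "assay_config"))
  m <- config$photos_per_sample
  mu <- assay_mean_response(config$conc_grid, config)
  with_seed(seed, {
    nconc <- length(config$conc_grid)
    reps <- matrix(
      stats::rnorm(nconc * m, mean = rep(mu, each = m), sd = config$noise_sd_gpi),
      nrow = nconc, byrow = TRUE
    )
    blanks <- rowMeans(matrix(
      stats::rnorm(config$n_blanks * m, 0, config$noise_sd_gpi),
      nrow = config$n_blanks
    ))
    points <- data.frame(
      sample_id = sprintf("s%02d", seq_len(nconc)),
      pigment = "total",
      chl = config$conc_grid,
      gpi_final = rowMeans(reps),
      stringsAsFactors = FALSE
    )
    for (j in seq_len(m)) points[[paste0("gpi_rep", j)]] <- reps[, j]
    list(
      points = points,
      blanks = blanks,
      truth = list(
        config = unclass(config),
        mean_response = stats::setNames(mu, points$sample_id),
        seed = as.integer(seed)
      )
    )
  })
}

#' Configuration for the synthetic flask renderer
#'
#' The renderer stands in for photographs of culture flasks on a white
#' background: the culture region's color is the background attenuated
#' channel-wise by Beer-Lambert factors `exp(-extinction_ch * chl)`, a lid
#' shadow multiplies all channels of its strip by a common factor (which
#' leaves GPI unchanged, as in the physical protocol), and Gaussian pixel
#' noise is added before clipping to 8-bit. The green extinction must be the
#' smallest so that GPI rises with pigment concentration.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param background_rgb Near-white background color, 8-bit channels (all
#'   >= 180).
#' @param shadow_attenuation Multiplicative factor (0, 1] applied to the
#'   shadowed culture strip.
#' @param channel_extinctions Named attenuation coefficients `c(r=, g=, b=)`
#'   per ug/ml; `g` must be strictly smaller than `r` and `b`.
#' @param pixel_noise_sd Pixel noise SD in 8-bit units.
#' @param culture_rect,shadow_rows Geometry: the culture rectangle
#'   `c(row0, col0, row1, col1)` (half-open, 0-based) and the number of its
#'   top rows covered by the lid shadow.
#' @param background_margin Horizontal gap (pixels) between the culture
#'   rectangle and the flanking background sampling rectangles.
#' @return A validated list of class `render_config`.
#' @export
render_config <- function(image_size = c(120L, 160L),
                          background_rgb = c(r = 242, g = 243, b = 245),
                          shadow_attenuation = 0.85,
                          channel_extinctions = c(r = 0.065, g = 0.028, b = 0.060),
                          pixel_noise_sd = 2,
                          culture_rect = NULL,
                          shadow_rows = 18L,
                          background_margin = 10L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 40L)) {
    stop_contract("image_size must be c(height, width) with both >= 40")
  }
  if (length(background_rgb) != 3L || any(background_rgb < 180) ||
      any(background_rgb > 255)) {
    stop_contract("background_rgb must be near-white (all channels in [180, 255])")
  }
  if (shadow_attenuation <= 0 || shadow_attenuation > 1) {
    stop_contract("shadow_attenuation must lie in (0, 1]")
  }
  e <- channel_extinctions
  if (length(e) != 3L || is.null(names(e)) ||
      !all(c("r", "g", "b") %in% names(e))) {
    stop_contract("channel_extinctions must be named c(r=, g=, b=)")
  }
  if (!(e[["g"]] < e[["r"]] && e[["g"]] < e[["b"]])) {
    stop_contract("green extinction must be smaller than red and blue ",
                  "(otherwise GPI would not rise with chlorophyll)")
  }
  if (pixel_noise_sd < 0) stop_contract("pixel_noise_sd must be non-negative")
  h <- image_size[1L]
  w <- image_size[2L]
  if (is.null(culture_rect)) {
    culture_rect <- c(round(h * 0.25), round(w * 0.35),
                      round(h * 0.92), round(w * 0.65))
  }
  culture_rect <- as.integer(culture_rect)
  if (culture_rect[1L] < 0L || culture_rect[2L] < 0L ||
      culture_rect[3L] > h || culture_rect[4L] > w ||
      culture_rect[3L] - culture_rect[1L] < 2L * shadow_rows) {
    stop_contract("culture_rect must fit inside the image and be at least ",
                  "twice shadow_rows tall")
  }
  bg_w <- max(10L, background_margin)
  left_rect <- c(culture_rect[1L],
                 max(0L, culture_rect[2L] - background_margin - 3L * bg_w),
                 culture_rect[3L],
                 culture_rect[2L] - background_margin)
  right_rect <- c(culture_rect[1L],
                  culture_rect[4L] + background_margin,
                  culture_rect[3L],
                  min(w, culture_rect[4L] + background_margin + 3L * bg_w))
  if (left_rect[4L] <= left_rect[2L] || right_rect[4L] <= right_rect[2L]) {
    stop_contract("image too narrow for flanking background regions")
  }
  structure(
    list(
      image_size = image_size,
      background_rgb = stats::setNames(as.numeric(background_rgb), c("r", "g", "b")),
      shadow_attenuation = shadow_attenuation,
      channel_extinctions = e[c("r", "g", "b")],
      pixel_noise_sd = pixel_noise_sd,
      culture_rect = culture_rect,
      shadow_rows = as.integer(shadow_rows),
      background_left = as.integer(left_rect),
      background_right = as.integer(right_rect)
    ),
    class = "render_config"
  )
}

#' Render a synthetic flask photograph
#'
#' @param chl_total Total chlorophyll concentration of the rendered culture
#'   (ug/ml, >= 0).
#' @param config A [render_config()].
#' @param seed Integer seed for the pixel noise.
#' @param photo_index,sample_id,role Metadata stamped into the returned
#'   annotation.
#' @return A list with `image` (8-bit integer array height x width x 3),
#'   `annotation` (a matching [photo_annotation()] with `image = NA`; attach a
#'   path after writing the PNG), `gpi_culture_truth` (noise-free,
#'   pre-quantization GPI of the lit culture color), and
#'   `gpi_background_truth`.
#' @export
render_flask_image <- function(chl_total, config = render_config(), seed = 1L,
                               photo_index = NA_integer_,
                               sample_id = NA_character_,
                               role = c("sample", "baseline")) {
  stopifnot(inherits(config, "render_config"))
  role <- match.arg(role)
  if (!is.finite(chl_total) || chl_total < 0) {
    stop_contract("chl_total must be non-negative")
  }
  h <- config$image_size[1L]
  w <- config$image_size[2L]
  bg <- config$background_rgb
  culture <- bg * exp(-config$channel_extinctions * chl_total)

  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  cr <- config$culture_rect
  rows <- (cr[1L] + 1L):cr[3L]
  cols <- (cr[2L] + 1L):cr[4L]
  shadow_rows <- rows[seq_len(config$shadow_rows)]
  lit_rows <- rows[-seq_len(config$shadow_rows)]
  for (ch in 1:3) {
    img[lit_rows, cols, ch] <- culture[ch]
    img[shadow_rows, cols, ch] <- culture[ch] * config$shadow_attenuation
  }

  img <- with_seed(seed, {
    img + array(stats::rnorm(h * w * 3L, 0, config$pixel_noise_sd),
                dim = dim(img))
  })
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"

  annotation <- photo_annotation(
    image = NA_character_,
    culture_shadow = c(cr[1L], cr[2L], cr[1L] + config$shadow_rows, cr[4L]),
    culture_lit = c(cr[1L] + config$shadow_rows, cr[2L], cr[3L], cr[4L]),
    background_left = config$background_left,
    background_right = config$background_right,
    role = role,
    sample_id = sample_id,
    photo_index = photo_index
  )
  list(
    image = img,
    annotation = annotation,
    gpi_culture_truth = unname(culture["g"] / sum(culture)),
    gpi_background_truth = unname(bg["g"] / sum(bg))
  )
}

#' Render a triplicate image dataset for a concentration series
#'
#' Renders 3 photographs per concentration plus a triplicate blank (media
#' only, chlorophyll 0) baseline flask, ready for [extract_gpi()].
#'
#' @param concentrations Chlorophyll concentrations (ug/ml).
#' @param config A [render_config()].
#' @param seed Integer seed.
#' @return A list with `annotations` (list of [photo_annotation()]), `images`
#'   (named list of arrays keyed by synthetic image ids matching the
#'   annotations' `image` fields), and `truth` (data frame: `sample_id`,
#'   `chl`, `gpi_culture_truth`, `gpi_sample_truth` = culture minus
#'   background GPI).
#' @export
render_image_dataset <- function(concentrations, config = render_config(),
                                 seed = 1L) {
  if (length(concentrations) == 0L || any(concentrations < 0)) {
    stop_contract("concentrations must be non-negative")
  }
  annotations <- list()
  images <- list()
  truth <- NULL
  add_triplet <- function(chl, sid, role, base_seed) {
    for (k in 1:3) {
      r <- render_flask_image(chl, config, seed = base_seed + k,
                              photo_index = k, sample_id = sid, role = role)
      key <- sprintf("synthetic://%s_p%d", sid, k)
      r$annotation$image <- key
      annotations[[length(annotations) + 1L]] <<- r$annotation
      images[[key]] <<- r$image
      if (k == 1L) {
        truth <<- rbind(truth, data.frame(
          sample_id = sid, chl = chl,
          gpi_culture_truth = r$gpi_culture_truth,
          gpi_sample_truth = r$gpi_culture_truth - r$gpi_background_truth,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  add_triplet(0, "baseline", "baseline", seed * 1000L)
  for (i in seq_along(concentrations)) {
    add_triplet(concentrations[i], sprintf("s%02d", i), "sample",
                seed * 1000L + 100L * i)
  }
  list(annotations = annotations, images = images, truth = truth)
}

#' Type-I error / power of the curve-comparison test by simulation
#'
#' Generates paired calibration datasets from a common true line (plus an
#' optional slope offset in the second group), runs [compare_curves()] on each
#' pair, and reports rejection rates with exact binomial confidence intervals.
#' Used to verify that the slope F-test holds its nominal size and to sanity
#' check power.
#'
#' @param n_per_group Points per group (x values equally spaced over
#'   `x_range`).
#' @param slope,intercept True line shared by both groups.
#' @param delta_slope Slope offset added to the second group (0 for a null
#'   simulation).
#' @param noise_sd Residual SD of the GPI noise.
#' @param replicates Number of simulated pairs (>= 100).
#' @param alpha Test level.
#' @param x_range Concentration range covered by each group.
#' @param seed Integer seed.
#' @return A list with `rejection_slope`, `rejection_intercept` (rate among
#'   replicates where the intercept test ran), counts, and 95% binomial
#'   confidence intervals.
#' @export
simulate_null_comparison <- function(n_per_group = 12L,
                                     slope = 0.00694, intercept = 0.000799,
                                     delta_slope = 0,
                                     noise_sd = 0.002,
                                     replicates = 1000L,
                                     alpha = 0.05,
                                     x_range = c(0.5, 16),
                                     seed = 1L) {
  if (!is_count(replicates) || replicates < 100) {
    stop_contract("replicates must be an integer >= 100")
  }
  x <- seq(x_range[1L], x_range[2L], length.out = n_per_group)
  mu1 <- slope * x + intercept
  mu2 <- (slope + delta_slope) * x + intercept
  with_seed(seed, {
    rej_slope <- 0L
    int_tested <- 0L
    rej_int <- 0L
    for (r in seq_len(replicates)) {
      g1 <- data.frame(chl = x, gpi_final = mu1 + stats::rnorm(n_per_group, 0, noise_sd))
      g2 <- data.frame(chl = x, gpi_final = mu2 + stats::rnorm(n_per_group, 0, noise_sd))
      cmp <- compare_curves(g1, g2, alpha = alpha)
      if (cmp$p_slope < alpha) rej_slope <- rej_slope + 1L
      if (!is.na(cmp$p_intercept)) {
        int_tested <- int_tested + 1L
        if (cmp$p_intercept < alpha) rej_int <- rej_int + 1L
      }
    }
    ci_slope <- stats::binom.test(rej_slope, replicates)$conf.int
    ci_int <- if (int_tested > 0L) {
      stats::binom.test(rej_int, int_tested)$conf.int
    } else {
      c(NA_real_, NA_real_)
    }
    list(
      replicates = replicates, alpha = alpha,
      rejections_slope = rej_slope,
      rejection_slope = rej_slope / replicates,
      ci_slope = as.numeric(ci_slope),
      intercept_tests = int_tested,
      rejections_intercept = rej_int,
      rejection_intercept = if (int_tested > 0L) rej_int / int_tested else NA_real_,
      ci_intercept = as.numeric(ci_int)
    )
  })
}
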