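#' Green pixel intensity of 8-bit RGB pixels
#'
#' Computes the green pixel intensity GPI = G / (R + G + B) for one or more
#' pixels. GPI is the dimensionless colorimetric response used throughout the
#' package: it is invariant under uniform scaling of all three channels (so
#' shading that darkens a flask multiplicatively leaves it unchanged), lies in
#' (0, 1], and equals exactly 1/3 for any achromatic (gray) pixel.
#'
#' @param pixels One pixel as a length-3 numeric vector `c(r, g, b)`, or many
#'   pixels as an n x 3 matrix or a data frame with columns `r`, `g`, `b`
#'   (and optionally `row`, `col`, used to name offending pixels in errors).
#' @return Numeric vector of GPI values, one per pixel.
#' @examples
#' green_pixel_intensity(c(100, 100, 100))  # 1/3
#' green_pixel_intensity(c(0, 255, 0))      # 1.0
#' @export
green_pixel_intensity <- function(pixels) {
  px <- as_pixel_matrix(pixels)
  rgb <- px$rgb
  total <- rowSums(rgb)
  bad <- which(total <= 0)
  if (length(bad) > 0L) {
    stop_contract(
      "invalid pixel (R+G+B = 0, black) at ",
      pixel_label(px, bad[1L]),
      ": GPI is undefined for zero-sum pixels"
    )
  }
  unname(rgb[, 2L] / total)
}

# Normalize pixel input to a list(rgb = n x 3 matrix, coords = NULL or n x 2).
as_pixel_matrix <- function(pixels) {
  coords <- NULL
  if (is.data.frame(pixels)) {
    need <- c("r", "g", "b")
    if (!all(need %in% names(pixels))) {
      stop_contract("pixel data frame must have columns r, g, b")
    }
    if (all(c("row", "col") %in% names(pixels))) {
      coords <- cbind(pixels$row, pixels$col)
    }
    rgb <- cbind(pixels$r, pixels$g, pixels$b)
  } else if (is.matrix(pixels)) {
    if (ncol(pixels) != 3L) stop_contract("pixel matrix must have 3 columns (r, g, b)")
    rgb <- pixels
  } else if (is.numeric(pixels) && length(pixels) == 3L) {
    rgb <- matrix(pixels, nrow = 1L)
  } else {
    stop_contract("pixels must be a length-3 vector, an n x 3 matrix, or a data frame")
  }
  storage.mode(rgb) <- "double"
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 255)) {
    stop_contract("pixel channel intensities must lie in [0, 255]")
  }
  list(rgb = rgb, coords = coords)
}

pixel_label <- function(px, i) {
  if (!is.null(px$coords)) {
    sprintf("(row %d, col %d)", as.integer(px$coords[i, 1L]), as.integer(px$coords[i, 2L]))
  } else {
    sprintf("index %d", i)
  }
}

#' Construct a photograph annotation
#'
#' An annotation localizes the pixel-sampling regions within one photograph of
#' a culture vessel against a white background: the shadowed and lit parts of
#' the culture (the flask lid casts a shadow across the top of the culture)
#' and the white background immediately left and right of the vessel.
#' Baseline-role photographs show a flask of growth medium without algae and
#' are used to zero the assay each sampling day.
#'
#' Regions are either half-open rectangles `c(row0, col0, row1, col1)` in
#' 0-based pixel coordinates (pixels with row0 <= row < row1, col0 <= col <
#' col1) or explicit n x 2 matrices of 0-based (row, col) pixel coordinates.
#'
#' @param image Path to the photograph (PNG), or `NA` if the image is passed
#'   directly to downstream functions.
#' @param culture_shadow,culture_lit,background_left,background_right Region
#'   specifications (rectangle vector or pixel matrix).
#' @param role `"sample"` for culture photographs, `"baseline"` for
#'   media-only flask photographs.
#' @param sample_id Optional sample identifier carried through to outputs.
#' @param photo_index Optional photograph number (1-3) within the triplicate.
#' @return An object of class `photo_annotation`.
#' @export
photo_annotation <- function(image = NA_character_,
                             culture_shadow,
                             culture_lit,
                             background_left,
                             background_right,
                             role = c("sample", "baseline"),
                             sample_id = NA_character_,
                             photo_index = NA_integer_) {
  role <- match.arg(role)
  regions <- list(
    culture_shadow = validate_region(culture_shadow, "culture_shadow"),
    culture_lit = validate_region(culture_lit, "culture_lit"),
    background_left = validate_region(background_left, "background_left"),
    background_right = validate_region(background_right, "background_right")
  )
  check_regions_disjoint(regions)
  structure(
    list(
      image = image,
      role = role,
      sample_id = sample_id,
      photo_index = as.integer(photo_index),
      regions = regions
    ),
    class = "photo_annotation"
  )
}

validate_region <- function(region, name) {
  if (is.matrix(region)) {
    if (ncol(region) != 2L || nrow(region) == 0L) {
      stop_contract("region '", name, "' pixel list must be a non-empty n x 2 matrix")
    }
    storage.mode(region) <- "integer"
    return(region)
  }
  if (is.numeric(region) && length(region) == 4L) {
    region <- as.integer(region)
    if (region[3L] <= region[1L] || region[4L] <= region[2L]) {
      stop_contract("region '", name, "' rectangle [row0, col0, row1, col1] is empty")
    }
    if (any(region[1:2] < 0L)) {
      stop_contract("region '", name, "' rectangle has negative coordinates")
    }
    return(region)
  }
  stop_contract("region '", name, "' must be a length-4 rectangle or an n x 2 pixel matrix")
}

# Enumerate all 0-based (row, col) pixels of a validated region.
region_pixels <- function(region) {
  if (is.matrix(region)) return(region)
  rows <- region[1L]:(region[3L] - 1L)
  cols <- region[2L]:(region[4L] - 1L)
  cbind(
    row = rep(rows, times = length(cols)),
    col = rep(cols, each = length(rows))
  )
}

check_regions_disjoint <- function(regions) {
  keys <- lapply(regions, function(r) {
    px <- region_pixels(r)
    px[, 1L] * 1e6 + px[, 2L]
  })
  all_keys <- unlist(keys, use.names = FALSE)
  if (anyDuplicated(all_keys)) {
    stop_contract("annotation regions overlap; regions must be disjoint")
  }
  invisible(TRUE)
}

#' Read a photograph as an 8-bit RGB array
#'
#' Reads a PNG image and returns an integer array `height x width x 3` with
#' channel intensities in 0-255. Deeper bit depths are rescaled to 8-bit;
#' grayscale images are expanded to three identical channels; an alpha
#' channel, if present, is composited over white to match the white-background
#' photographic protocol.
#'
#' @param path Path to a PNG file.
#' @return Integer array `c(height, width, 3)`.
#' @export
read_photo <- function(path) {
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop_contract("only PNG images are supported; got: ", basename(path))
  }
  if (!file.exists(path)) stop_contract("image file not found: ", path)
  img <- png::readPNG(path)
  as_photo_array(img)
}

# Normalize a decoded image (values in [0,1], 2 or 3 dims, 1-4 channels) to
# an 8-bit integer height x width x 3 array.
as_photo_array <- function(img) {
  if (is.integer(img) && length(dim(img)) == 3L && dim(img)[3L] == 3L) {
    if (any(img < 0L) || any(img > 255L)) {
      stop_contract("integer image values must lie in [0, 255]")
    }
    return(img)
  }
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  nc <- dim(img)[3L]
  if (nc == 2L) {  # gray + alpha
    img <- array(c(rep(img[, , 1L], 3L), img[, , 2L]), dim = c(dim(img)[1:2], 4L))
    nc <- 4L
  }
  if (nc == 4L) {  # composite over white background
    alpha <- img[, , 4L]
    out <- array(0, dim = c(dim(img)[1:2], 3L))
    for (ch in 1:3) out[, , ch] <- img[, , ch] * alpha + (1 - alpha)
    img <- out
  } else if (nc != 3L) {
    stop_contract("unsupported channel count: ", nc)
  }
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Sample culture and background pixels from an annotated photograph
#'
#' Draws the pixel sample the manual protocol prescribes: 3 culture pixels
#' (stratified so that both the shadowed and the lit culture region are
#' represented; with two strata the larger region contributes 2 pixels and
#' the smaller 1, ties going to the shadowed region) and 6 background pixels
#' (3 from the white background left of the vessel, 3 from the right).
#' Selection is a seeded random draw from the annotated regions, so results
#' are reproducible.
#'
#' @param image An image array as returned by [read_photo()], or a path to a
#'   PNG file. If `NULL`, the annotation's `image` path is read.
#' @param annotation A [photo_annotation()].
#' @param seed Integer seed making the draw deterministic.
#' @return A data frame with columns `region`, `row`, `col` (0-based), `r`,
#'   `g`, `b`: 3 culture rows followed by 6 background rows.
#' @export
sample_region_pixels <- function(image = NULL, annotation, seed) {
  if (!inherits(annotation, "photo_annotation")) {
    stop_contract("annotation must be a photo_annotation object")
  }
  if (is.null(image)) image <- annotation$image
  if (is.character(image)) image <- read_photo(image)
  image <- as_photo_array(image)
  h <- dim(image)[1L]
  w <- dim(image)[2L]

  px_sets <- lapply(annotation$regions, region_pixels)
  for (nm in names(px_sets)) {
    px <- px_sets[[nm]]
    if (nrow(px) == 0L) stop_contract("region '", nm, "' is empty")
    if (any(px[, 1L] < 0L) || any(px[, 2L] < 0L) ||
        any(px[, 1L] >= h) || any(px[, 2L] >= w)) {
      stop_contract(
        "region '", nm, "' extends outside the ", h, " x ", w, " image"
      )
    }
  }

  n_shadow <- nrow(px_sets$culture_shadow)
  n_lit <- nrow(px_sets$culture_lit)
  alloc_shadow <- if (n_shadow >= n_lit) 2L else 1L
  alloc_lit <- 3L - alloc_shadow

  with_seed(seed, {
    picked <- rbind(
      draw_pixels(px_sets$culture_shadow, alloc_shadow),
      draw_pixels(px_sets$culture_lit, alloc_lit),
      draw_pixels(px_sets$background_left, 3L),
      draw_pixels(px_sets$background_right, 3L)
    )
    region <- c(
      rep("culture_shadow", alloc_shadow),
      rep("culture_lit", alloc_lit),
      rep("background_left", 3L),
      rep("background_right", 3L)
    )
    data.frame(
      region = region,
      row = picked[, 1L],
      col = picked[, 2L],
      r = image[cbind(picked[, 1L] + 1L, picked[, 2L] + 1L, 1L)],
      g = image[cbind(picked[, 1L] + 1L, picked[, 2L] + 1L, 2L)],
      b = image[cbind(picked[, 1L] + 1L, picked[, 2L] + 1L, 3L)],
      stringsAsFactors = FALSE
    )
  })
}

# Draw n pixels from an enumerated region, without replacement when possible.
draw_pixels <- function(pixels, n) {
  idx <- sample.int(nrow(pixels), n, replace = nrow(pixels) < n)
  pixels[idx, , drop = FALSE]
}

#' Background-corrected green pixel intensity of one photograph
#'
#' Averages the GPI of the 3 culture pixels and of the 6 background pixels and
#' reports their difference: `gpi_sample = gpi_culture - gpi_background`. The
#' same arithmetic applied to a media-only flask yields the day's baseline
#' reading.
#'
#' @param culture_pixels Exactly 3 pixels (any format accepted by
#'   [green_pixel_intensity()]); for convenience a data frame from
#'   [sample_region_pixels()] may be passed as `culture_pixels` with
#'   `background_pixels` missing, in which case rows are split by region.
#' @param background_pixels Exactly 6 pixels.
#' @param photo_index Optional photograph number within the triplicate.
#' @return An object of class `gpi_reading`: a list with `gpi_culture`,
#'   `gpi_background`, `gpi_sample` and `photo_index`.
#' @export
gpi_of_photo <- function(culture_pixels, background_pixels = NULL,
                         photo_index = NA_integer_) {
  if (is.null(background_pixels) && is.data.frame(culture_pixels) &&
      "region" %in% names(culture_pixels)) {
    is_bg <- grepl("^background", culture_pixels$region)
    background_pixels <- culture_pixels[is_bg, , drop = FALSE]
    culture_pixels <- culture_pixels[!is_bg, , drop = FALSE]
  }
  gpi_c <- green_pixel_intensity(culture_pixels)
  gpi_b <- green_pixel_intensity(background_pixels)
  if (length(gpi_c) != 3L) {
    stop_contract("exactly 3 culture pixels are required, got ", length(gpi_c))
  }
  if (length(gpi_b) != 6L) {
    stop_contract("exactly 6 background pixels are required, got ", length(gpi_b))
  }
  structure(
    list(
      gpi_culture = mean(gpi_c),
      gpi_background = mean(gpi_b),
      gpi_sample = mean(gpi_c) - mean(gpi_b),
      photo_index = as.integer(photo_index)
    ),
    class = "gpi_reading"
  )
}

#' Final green pixel intensity of a sample
#'
#' Combines the triplicate photographs of a sample with the triplicate
#' photographs of the day's media-only baseline flask:
#' `gpi_final = mean(sample gpi_sample) - mean(baseline gpi_sample)`.
#' Negative values are retained (not floored at zero) so that blank-replicate
#' distributions used for the limit of blank remain unbiased.
#'
#' @param sample_readings List of exactly 3 `gpi_reading` objects from the
#'   sample photographs.
#' @param baseline_readings List of exactly 3 `gpi_reading` objects from the
#'   baseline photographs.
#' @param sample_id Optional identifier.
#' @return An object of class `sample_gpi`: a list with `sample_id`,
#'   `gpi_final`, `baseline_mean` and `per_photo_gpi` (the 3 sample readings).
#' @export
gpi_final <- function(sample_readings, baseline_readings,
                      sample_id = NA_character_) {
  check_reading_triplet <- function(x, what) {
    if (!is.list(x) || length(x) != 3L ||
        !all(vapply(x, inherits, logical(1), "gpi_reading"))) {
      stop_contract("exactly 3 ", what, " gpi_reading objects are required")
    }
  }
  check_reading_triplet(sample_readings, "sample")
  check_reading_triplet(baseline_readings, "baseline")
  sample_mean <- mean(vapply(sample_readings, `[[`, numeric(1), "gpi_sample"))
  baseline_mean <- mean(vapply(baseline_readings, `[[`, numeric(1), "gpi_sample"))
  structure(
    list(
      sample_id = sample_id,
      gpi_final = sample_mean - baseline_mean,
      baseline_mean = baseline_mean,
      per_photo_gpi = sample_readings
    ),
    class = "sample_gpi"
  )
}

#' @export
print.gpi_reading <- function(x, ...) {
  cat(sprintf(
    "GPI reading (photo %s): culture %.5f, background %.5f, corrected %.5f\n",
    ifelse(is.na(x$photo_index), "?", x$photo_index),
    x$gpi_culture, x$gpi_background, x$gpi_sample
  ))
  invisible(x)
}

#' @export
print.sample_gpi <- function(x, ...) {
  cat(sprintf(
    "Sample %s: final GPI %.5f (baseline %.5f)\n",
    x$sample_id, x$gpi_final, x$baseline_mean
  ))
  invisible(x)
}

#' Read a photograph annotation from JSON
#'
#' The on-disk annotation format is one JSON document per photograph:
#' `{"image": path, "role": "sample"|"baseline", "sample_id": id,
#' "photo_index": k, "regions": {"culture_shadow": [row0, col0, row1, col1],
#' "culture_lit": ..., "background_left": ..., "background_right": ...}}`
#' with rectangles half-open and 0-based. A region may also be given as an
#' array of `[row, col]` pixel pairs. Relative image paths are resolved
#' against the annotation file's directory.
#'
#' @param path Path to the JSON annotation.
#' @return A [photo_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_contract("annotation file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("image", "role", "regions")
  if (!all(need %in% names(doc))) {
    stop_contract("annotation ", basename(path),
                  " must contain fields: ", paste(need, collapse = ", "))
  }
  image <- doc$image
  if (is.null(image) || length(image) != 1L) image <- NA_character_
  if (!is.na(image) && !grepl("^(/|[A-Za-z]:)", image)) {
    image <- file.path(dirname(path), image)
  }
  as_region <- function(x) {
    if (is.matrix(x)) x else as.numeric(x)
  }
  photo_annotation(
    image = image,
    culture_shadow = as_region(doc$regions$culture_shadow),
    culture_lit = as_region(doc$regions$culture_lit),
    background_left = as_region(doc$regions$background_left),
    background_right = as_region(doc$regions$background_right),
    role = doc$role,
    sample_id = if (!is.null(doc$sample_id)) doc$sample_id else NA_character_,
    photo_index = if (!is.null(doc$photo_index)) doc$photo_index else NA_integer_
  )
}

#' Write a photograph annotation to JSON
#'
#' @param annotation A [photo_annotation()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "photo_annotation"))
  doc <- list(
    image = annotation$image,
    role = annotation$role,
    sample_id = annotation$sample_id,
    photo_index = annotation$photo_index,
    regions = annotation$regions
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Extract final GPI values from annotated photograph sets
#'
#' Runs the full image pipeline for a set of annotations: per photograph,
#' seeded pixel sampling and background correction; per sample, triplicate
#' averaging; finally baseline subtraction using the baseline-role
#' annotations. Exactly 3 photographs per sample and 3 baseline photographs
#' are required.
#'
#' @param annotations List of [photo_annotation()] objects (or character
#'   vector of JSON paths), mixing sample and baseline roles. Sample
#'   membership is taken from `sample_id`.
#' @param seed Integer seed; each photograph uses a sub-seed derived from it.
#' @param images Optional named list mapping annotation image paths to
#'   in-memory arrays (used by the synthetic pipeline to avoid disk I/O).
#' @return A data frame with one row per sample photograph: `sample_id`,
#'   `photo_index`, `gpi_culture`, `gpi_background`, `gpi_sample`,
#'   `gpi_final` (the per-sample value, repeated across its 3 rows).
#' @export
extract_gpi <- function(annotations, seed = 1L, images = NULL) {
  if (is.character(annotations)) {
    annotations <- lapply(annotations, read_annotation)
  }
  if (!all(vapply(annotations, inherits, logical(1), "photo_annotation"))) {
    stop_contract("annotations must be photo_annotation objects or JSON paths")
  }
  roles <- vapply(annotations, `[[`, character(1), "role")
  baselines <- annotations[roles == "baseline"]
  samples <- annotations[roles == "sample"]
  if (length(baselines) != 3L) {
    stop_contract("exactly 3 baseline-role photographs are required, got ",
                  length(baselines))
  }
  if (length(samples) == 0L) stop_contract("no sample-role photographs supplied")

  reading_of <- function(ann, k) {
    img <- NULL
    if (!is.null(images) && !is.na(ann$image) && ann$image %in% names(images)) {
      img <- images[[ann$image]]
    }
    px <- sample_region_pixels(img, ann, seed = seed + 7L * k)
    gpi_of_photo(px, photo_index = ann$photo_index)
  }

  baseline_readings <- lapply(seq_along(baselines), function(k) {
    reading_of(baselines[[k]], k)
  })

  ids <- vapply(samples, `[[`, character(1), "sample_id")
  out <- list()
  for (sid in unique(ids)) {
    grp <- samples[ids == sid]
    if (length(grp) != 3L) {
      stop_contract("sample '", sid, "' has ", length(grp),
                    " photographs; exactly 3 are required")
    }
    ord <- order(vapply(grp, `[[`, integer(1), "photo_index"))
    grp <- grp[ord]
    readings <- lapply(seq_along(grp), function(k) {
      reading_of(grp[[k]], 1000L * match(sid, unique(ids)) + k)
    })
    sg <- gpi_final(readings, baseline_readings, sample_id = sid)
    out[[sid]] <- data.frame(
      sample_id = sid,
      photo_index = vapply(readings, `[[`, integer(1), "photo_index"),
      gpi_culture = vapply(readings, `[[`, numeric(1), "gpi_culture"),
      gpi_background = vapply(readings, `[[`, numeric(1), "gpi_background"),
      gpi_sample = vapply(readings, `[[`, numeric(1), "gpi_sample"),
      gpi_final = sg$gpi_final,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
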