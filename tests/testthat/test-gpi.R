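test_that("green pixel intensity handles achromatic, pure and scaled pixels", {
  expect_equal(green_pixel_intensity(c(100, 100, 100)), 1 / 3)
  expect_equal(green_pixel_intensity(c(0, 255, 0)), 1)
  expect_equal(green_pixel_intensity(c(255, 255, 255)),
               green_pixel_intensity(c(10, 10, 10)))
  m <- rbind(c(10, 40, 30), c(1, 2, 3))
  expect_equal(green_pixel_intensity(m), c(40 / 80, 2 / 6))
})

test_that("GPI is scale invariant and bounded on random valid pixels", {
  set.seed(11)
  for (i in 1:50) {
    px <- sample.int(85, 3)  # k = 3 scaling stays within 8 bits
    g1 <- green_pixel_intensity(px)
    g3 <- green_pixel_intensity(px * 3L)
    expect_true(g1 > 0 && g1 <= 1)
    expect_equal(g1, g3, tolerance = 1e-12)
  }
})

test_that("a black pixel raises an error naming the offending coordinate", {
  df <- data.frame(r = c(10, 0), g = c(20, 0), b = c(30, 0),
                   row = c(4, 7), col = c(1, 9))
  expect_error(green_pixel_intensity(df), "row 7, col 9")
  expect_error(green_pixel_intensity(c(0, 0, 0)), "invalid pixel")
  expect_error(green_pixel_intensity(c(-1, 4, 4)), "\\[0, 255\\]")
})

test_that("per-photo GPI matches hand arithmetic and a brute-force mean", {
  culture <- rbind(pixel_with_gpi(40, 100),   # GPI 0.40
                   pixel_with_gpi(42, 100),   # GPI 0.42
                   pixel_with_gpi(44, 100))   # GPI 0.44
  background <- matrix(rep(85, 18), ncol = 3) # GPI 1/3 each
  rd <- gpi_of_photo(culture, background)
  expect_equal(rd$gpi_culture, 0.42, tolerance = 1e-12)
  expect_equal(rd$gpi_sample, 0.42 - 1 / 3, tolerance = 1e-12)

  # brute force: per-pixel ratio then mean, computed without the package
  bf_culture <- mean(culture[, 2] / rowSums(culture))
  bf_bg <- mean(background[, 2] / rowSums(background))
  expect_equal(rd$gpi_culture, bf_culture, tolerance = 1e-12)
  expect_equal(rd$gpi_sample, bf_culture - bf_bg, tolerance = 1e-12)

  # blank flask: culture indistinguishable from background
  blank <- gpi_of_photo(background[1:3, ], background)
  expect_equal(blank$gpi_sample, 0, tolerance = 1e-12)

  expect_error(gpi_of_photo(culture[1:2, ], background), "3 culture")
  expect_error(gpi_of_photo(culture, background[1:5, ]), "6 background")
})

test_that("final GPI subtracts the baseline mean and may be negative", {
  s <- lapply(c(0.05, 0.06, 0.07), make_reading)
  b <- lapply(c(0.00, 0.01, -0.01), make_reading)
  sg <- gpi_final(s, b, sample_id = "x")
  expect_equal(sg$gpi_final, 0.06, tolerance = 1e-12)
  expect_equal(sg$baseline_mean, 0, tolerance = 1e-12)

  same <- gpi_final(s, s)
  expect_equal(same$gpi_final, 0, tolerance = 1e-12)

  neg <- gpi_final(b, s)
  expect_lt(neg$gpi_final, 0)

  expect_error(gpi_final(s[1:2], b), "exactly 3")
})

test_that("adding a constant to all pixel GPIs leaves the corrected GPI fixed", {
  base <- lapply(c(0.02, 0.03, 0.04), make_reading)
  shifted <- lapply(base, function(r) {
    r$gpi_culture <- r$gpi_culture + 0.1
    r$gpi_background <- r$gpi_background + 0.1
    r  # gpi_sample unchanged by construction of the difference
  })
  expect_equal(
    gpi_final(base, lapply(c(0, 0, 0), make_reading))$gpi_final,
    gpi_final(shifted, lapply(c(0, 0, 0), make_reading))$gpi_final,
    tolerance = 1e-12
  )
})

test_that("pixel sampling is stratified, deterministic and validated", {
  img <- make_uniform_image()
  ann <- make_uniform_annotation()
  px <- sample_region_pixels(img, ann, seed = 5)
  expect_equal(nrow(px), 9L)
  expect_equal(sum(px$region == "culture_shadow") +
                 sum(px$region == "culture_lit"), 3L)
  expect_gte(sum(px$region == "culture_shadow"), 1L)
  expect_gte(sum(px$region == "culture_lit"), 1L)
  expect_equal(sum(px$region == "background_left"), 3L)
  expect_equal(sum(px$region == "background_right"), 3L)

  # constant image: all culture pixels are the fill color
  expect_true(all(px$g[1:3] == 110))
  expect_true(all(px$r[4:9] == 240))

  # determinism and seed sensitivity of the coordinates
  px2 <- sample_region_pixels(img, ann, seed = 5)
  expect_identical(px, px2)
  px3 <- sample_region_pixels(img, ann, seed = 6)
  expect_false(identical(px[, c("row", "col")], px3[, c("row", "col")]))

  # stratification holds for any seed on a noisy image
  noisy <- img
  set.seed(1)
  noisy[, , 2] <- pmin(255L, noisy[, , 2] + sample(0:5, length(noisy[, , 2]), TRUE))
  for (s in 1:5) {
    pxn <- sample_region_pixels(noisy, ann, seed = s)
    expect_gte(sum(pxn$region == "culture_shadow"), 1L)
    expect_gte(sum(pxn$region == "culture_lit"), 1L)
  }

  bad <- photo_annotation(
    culture_shadow = c(20, 30, 30, 50), culture_lit = c(30, 30, 50, 50),
    background_left = c(20, 5, 50, 25), background_right = c(20, 55, 50, 90)
  )
  expect_error(sample_region_pixels(img, bad, seed = 1), "outside")
})

test_that("annotations validate geometry and survive a JSON roundtrip", {
  expect_error(
    photo_annotation(culture_shadow = c(0, 0, 10, 10),
                     culture_lit = c(5, 5, 15, 15),
                     background_left = c(0, 20, 10, 30),
                     background_right = c(0, 40, 10, 50)),
    "overlap"
  )
  expect_error(
    photo_annotation(culture_shadow = c(10, 10, 10, 20),
                     culture_lit = c(20, 10, 30, 20),
                     background_left = c(0, 0, 10, 5),
                     background_right = c(0, 40, 10, 50)),
    "empty"
  )

  ann <- make_uniform_annotation()
  path <- withr::local_tempfile(fileext = ".json")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(back$regions, ann$regions)
  expect_equal(back$role, ann$role)
})

test_that("PNG photographs round-trip through read_photo", {
  img <- make_uniform_image()
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img / 255, path)
  back <- read_photo(path)
  expect_identical(back, img)
  expect_error(read_photo(sub("png$", "jpg", path)), "PNG")
})

test_that("alpha channels are composited over white", {
  rgba <- array(0, dim = c(4, 4, 4))
  rgba[, , 2] <- 0.5   # half-intensity green
  rgba[, , 4] <- 0.5   # half transparent
  arr <- gpical:::as_photo_array(rgba)
  # channel = 0.5 * 0.5 + 0.5 = 0.75 for green, 0 * 0.5 + 0.5 = 0.5 for r/b
  expect_true(all(arr[, , 2] == 191L))
  expect_true(all(arr[, , 1] == 128L))
})

test_that("the image pipeline extracts per-sample GPI from annotation sets", {
  culture_rgb <- c(60, 110, 60)
  img_sample <- make_uniform_image(culture = culture_rgb, shadow_scale = 0.8)
  img_blank <- make_uniform_image(culture = c(240, 240, 240))

  anns <- list()
  imgs <- list()
  for (k in 1:3) {
    a <- make_uniform_annotation(role = "baseline", sample_id = "base",
                                 photo_index = k)
    a$image <- paste0("mem://blank", k)
    anns[[length(anns) + 1]] <- a
    imgs[[a$image]] <- img_blank
    b <- make_uniform_annotation(role = "sample", sample_id = "s1",
                                 photo_index = k)
    b$image <- paste0("mem://s1_", k)
    anns[[length(anns) + 1]] <- b
    imgs[[b$image]] <- img_sample
  }
  res <- extract_gpi(anns, seed = 3, images = imgs)
  expect_equal(nrow(res), 3L)
  expect_equal(unique(res$sample_id), "s1")
  # uniform colors: corrected GPI is exactly the culture ratio minus 1/3
  # (the shadow strip scales all channels, leaving GPI unchanged)
  truth <- culture_rgb[2] / sum(culture_rgb) - 1 / 3
  expect_equal(unique(round(res$gpi_sample, 10)),
               round(truth, 10), tolerance = 1e-6)
  expect_equal(res$gpi_final[1], truth, tolerance = 1e-6)
})
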