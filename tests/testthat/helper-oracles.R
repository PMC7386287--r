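# Independent oracles and small fixture builders used across the test files.

# Brute-force OLS by iteratively refined grid search minimizing the sum of
# squared errors directly. The search runs over (slope, level at mean(x)),
# where the SSE surface is axis-aligned, so plain grid refinement converges;
# the intercept is recovered afterwards. Independent of lm() and of any
# closed-form normal equations.
brute_force_ols <- function(x, y, rounds = 14L, span = NULL, grid_n = 41L) {
  xc <- x - mean(x)
  slope <- (y[which.max(x)] - y[which.min(x)]) / (max(x) - min(x))
  level <- mean(y)
  if (is.null(span)) span <- max(abs(slope), abs(level), 1)
  sse <- function(s, m) sum((y - (s * xc + m))^2)
  for (r in seq_len(rounds)) {
    best <- c(slope, level, sse(slope, level))
    for (s in slope + seq(-span, span, length.out = grid_n)) {
      for (m in level + seq(-span, span, length.out = grid_n)) {
        v <- sse(s, m)
        if (v < best[3L]) best <- c(s, m, v)
      }
    }
    slope <- best[1L]
    level <- best[2L]
    span <- span / 8
  }
  list(slope = slope, intercept = level - slope * mean(x),
       sse = sse(slope, level))
}

# Independent OLS sum of squared errors via explicit normal equations on a
# design matrix (no lm()); used for the nested-model F oracle.
sse_of_design <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

# F statistics for the slope (interaction) and intercept (group) tests from
# nested residual sums of squares, built from scratch.
nested_f_oracle <- function(ctl, var_) {
  y <- c(ctl$gpi_final, var_$gpi_final)
  x <- c(ctl$chl, var_$chl)
  g <- c(rep(0, nrow(ctl)), rep(1, nrow(var_)))
  n <- length(y)
  X_full <- cbind(1, g, x, g * x)
  X_slope <- cbind(1, g, x)
  X_line <- cbind(1, x)
  sse_full <- sse_of_design(X_full, y)
  sse_slope <- sse_of_design(X_slope, y)
  sse_line <- sse_of_design(X_line, y)
  f_slope <- ((sse_slope - sse_full) / 1) / (sse_full / (n - 4))
  f_int <- ((sse_line - sse_slope) / 1) / (sse_slope / (n - 3))
  list(
    f_slope = f_slope,
    p_slope = stats::pf(f_slope, 1, n - 4, lower.tail = FALSE),
    f_intercept = f_int,
    p_intercept = stats::pf(f_int, 1, n - 3, lower.tail = FALSE)
  )
}

# A flat-color test image with the standard four annotated regions.
make_uniform_image <- function(culture = c(60, 110, 60),
                               background = c(240, 240, 240),
                               shadow_scale = 1) {
  img <- array(0L, dim = c(60L, 80L, 3L))
  for (ch in 1:3) img[, , ch] <- as.integer(background[ch])
  # culture rectangle rows 20..49, cols 30..49 (1-based); shadow = top 10 rows
  for (ch in 1:3) {
    img[21:30, 31:50, ch] <- as.integer(round(culture[ch] * shadow_scale))
    img[31:50, 31:50, ch] <- as.integer(culture[ch])
  }
  img
}

make_uniform_annotation <- function(role = "sample", sample_id = "s1",
                                    photo_index = 1L) {
  photo_annotation(
    culture_shadow = c(20, 30, 30, 50),
    culture_lit = c(30, 30, 50, 50),
    background_left = c(20, 5, 50, 25),
    background_right = c(20, 55, 50, 75),
    role = role, sample_id = sample_id, photo_index = photo_index
  )
}

# A gpi_reading with a prescribed corrected GPI, for arithmetic tests.
make_reading <- function(gpi_sample, photo_index = 1L) {
  structure(
    list(gpi_culture = gpi_sample + 1 / 3, gpi_background = 1 / 3,
         gpi_sample = gpi_sample, photo_index = as.integer(photo_index)),
    class = "gpi_reading"
  )
}

# Pixels with an exact target GPI (integer channels): g green, (s - g)/2 each
# for red and blue, requiring s - g even.
pixel_with_gpi <- function(g, s) {
  stopifnot((s - g) %% 2 == 0)
  c((s - g) / 2, g, (s - g) / 2)
}
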