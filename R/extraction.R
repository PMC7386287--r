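# Reference chlorophyll quantification from solvent-extraction absorbances.
#
# Extraction in 80% (v/v) acetone / 20% methanol; absorbances at 663.6 and
# 646.6 nm, each corrected by the 750 nm reading for turbidity. The extinction
# coefficient set (Porra) gives, per ml of original culture:
#   chl a   = (12.25 E663.6 -  2.55 E646.6) * extract_volume / culture_volume
#   chl b   = (20.31 E646.6 -  4.91 E663.6) * extract_volume / culture_volume
#   chl a+b = (17.76 E646.6 +  7.34 E663.6) * extract_volume / culture_volume
# The total coefficients are exactly the column sums (12.25 - 4.91 = 7.34,
# 20.31 - 2.55 = 17.76), so chl_total == chl_a + chl_b identically.

porra_coef <- matrix(
  c(12.25, -2.55,
    -4.91, 20.31),
  nrow = 2L, byrow = TRUE,
  dimnames = list(c("chl_a", "chl_b"), c("E663.6", "E646.6"))
)

#' Chlorophyll concentrations from extraction absorbances
#'
#' Converts spectrophotometer readings of an acetone/methanol chlorophyll
#' extract into chlorophyll a, b and total concentrations in micrograms per ml
#' of the original culture. Absorbances at 663.6 and 646.6 nm are first
#' corrected by subtracting the 750 nm (turbidity) reading.
#'
#' @param a663_6,a646_6,a750 Absorbance readings (vectors recycle in the usual
#'   way). `a750` defaults to 0.
#' @param culture_volume_ml Volume of culture pelleted for extraction (ml).
#' @param extract_volume_ml Volume of solvent the pellet was resuspended in
#'   (ml); the printed single-volume form of the equations corresponds to the
#'   default of 1 ml.
#' @return A data frame with columns `chl_a`, `chl_b`, `chl_total` (ug/ml of
#'   original culture). Values can be slightly negative for noisy near-blank
#'   extracts and are reported as-is.
#' @examples
#' chlorophyll_from_absorbance(1.0, 0.5)  # chl_a = 12.25 - 1.275 = 10.975
#' @export
chlorophyll_from_absorbance <- function(a663_6, a646_6, a750 = 0,
                                        culture_volume_ml = 1,
                                        extract_volume_ml = 1) {
  n <- max(length(a663_6), length(a646_6), length(a750),
           length(culture_volume_ml), length(extract_volume_ml))
  a663_6 <- rep_len(a663_6, n)
  a646_6 <- rep_len(a646_6, n)
  a750 <- rep_len(a750, n)
  culture_volume_ml <- rep_len(culture_volume_ml, n)
  extract_volume_ml <- rep_len(extract_volume_ml, n)

  if (any(!is.finite(culture_volume_ml)) || any(culture_volume_ml <= 0)) {
    stop_contract("culture_volume_ml must be positive")
  }
  if (any(!is.finite(extract_volume_ml)) || any(extract_volume_ml <= 0)) {
    stop_contract("extract_volume_ml must be positive")
  }
  if (any(c(a663_6, a646_6, a750) < 0)) {
    stop_contract("absorbances must be non-negative")
  }
  if (any(pmax(a663_6, a646_6) >= 1.0)) {
    warning("absorbance >= 1.00: outside the recommended working range; ",
            "dilute the extract", call. = FALSE)
  }

  e663 <- a663_6 - a750
  e646 <- a646_6 - a750
  if (any(e663 < 0) || any(e646 < 0)) {
    warning("negative corrected absorbance (A750 exceeds a pigment band); ",
            "results may be unreliable", call. = FALSE)
  }

  scale <- extract_volume_ml / culture_volume_ml
  chl_a <- (porra_coef["chl_a", 1L] * e663 + porra_coef["chl_a", 2L] * e646) * scale
  chl_b <- (porra_coef["chl_b", 1L] * e663 + porra_coef["chl_b", 2L] * e646) * scale
  data.frame(chl_a = chl_a, chl_b = chl_b, chl_total = chl_a + chl_b)
}

#' Extraction absorbances reproducing given chlorophyll concentrations
#'
#' Exact inverse of [chlorophyll_from_absorbance()]: solves the 2 x 2 linear
#' system for the corrected absorbances (E663.6, E646.6) that yield the
#' requested chlorophyll a and b concentrations, reporting them with
#' `a750 = 0`. The coefficient matrix has determinant
#' 12.25 * 20.31 - 2.55 * 4.91 = 236.277, so the solution always exists and is
#' unique. Used to manufacture synthetic spectrophotometry records with known
#' ground truth.
#'
#' @param chl_a,chl_b Target concentrations (ug/ml of original culture).
#' @param culture_volume_ml,extract_volume_ml Volumes as in the forward
#'   computation.
#' @return A data frame with columns `a663_6`, `a646_6`, `a750`,
#'   `culture_volume_ml`, `extract_volume_ml`.
#' @export
absorbance_from_chlorophyll <- function(chl_a, chl_b,
                                        culture_volume_ml = 1,
                                        extract_volume_ml = 1) {
  n <- max(length(chl_a), length(chl_b),
           length(culture_volume_ml), length(extract_volume_ml))
  chl_a <- rep_len(chl_a, n)
  chl_b <- rep_len(chl_b, n)
  culture_volume_ml <- rep_len(culture_volume_ml, n)
  extract_volume_ml <- rep_len(extract_volume_ml, n)
  if (any(culture_volume_ml <= 0) || any(extract_volume_ml <= 0)) {
    stop_contract("volumes must be positive")
  }
  # Per-extract pigment mass densities the absorbances must explain.
  scale <- culture_volume_ml / extract_volume_ml
  rhs <- rbind(chl_a * scale, chl_b * scale)
  sol <- solve(porra_coef, rhs)
  data.frame(
    a663_6 = sol[1L, ],
    a646_6 = sol[2L, ],
    a750 = 0,
    culture_volume_ml = culture_volume_ml,
    extract_volume_ml = extract_volume_ml
  )
}

#' Batch chlorophyll computation from an absorbance table
#'
#' @param absorbances Data frame with columns `sample_id`, `a663_6`, `a646_6`,
#'   and optionally `a750` (default 0), `culture_volume_ml` (default 1),
#'   `extract_volume_ml` (default 1).
#' @return The input columns plus `chl_a`, `chl_b`, `chl_total`.
#' @export
chlorophyll_table <- function(absorbances) {
  need <- c("a663_6", "a646_6")
  if (!is.data.frame(absorbances) || !all(need %in% names(absorbances))) {
    stop_contract("absorbance table must have columns a663_6, a646_6")
  }
  a750 <- if ("a750" %in% names(absorbances)) absorbances$a750 else 0
  cv <- if ("culture_volume_ml" %in% names(absorbances)) {
    absorbances$culture_volume_ml
  } else 1
  ev <- if ("extract_volume_ml" %in% names(absorbances)) {
    absorbances$extract_volume_ml
  } else 1
  res <- chlorophyll_from_absorbance(absorbances$a663_6, absorbances$a646_6,
                                     a750, cv, ev)
  cbind(absorbances, res)
}
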