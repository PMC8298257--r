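#' Octahedral shear strain
#'
#' Rotation-invariant distortional strain measure computed from the small
#' strain tensor,
#' \deqn{\gamma = \tfrac{2}{3}\sqrt{(e_{11}-e_{22})^2 + (e_{22}-e_{33})^2 +
#' (e_{11}-e_{33})^2 + 6e_{12}^2 + 6e_{23}^2 + 6e_{13}^2}.}
#' The shear terms enter squared; `strict = TRUE` switches to an alternative
#' form with unsquared shear terms that circulates in the mechanoregulation
#' literature, which is dimensionally inconsistent and can produce a
#' negative radicand (then truncated at zero). It is off by default and
#' exists only for comparison.
#'
#' @param e Numeric matrix (n x 6) or length-6 vector of tensor components
#'   in the order `e11, e22, e33, e12, e23, e13`.
#' @param strict Use the unsquared-shear variant (not recommended).
#' @return Octahedral shear strain, `>= 0`.
#' @export
#' @examples
#' octahedral_shear(c(0.03, 0, 0, 0, 0, 0))  # (2*sqrt(2)/3) * 0.03
octahedral_shear <- function(e, strict = FALSE) {
  if (is.null(dim(e))) e <- matrix(e, ncol = 6)
  stopifnot(ncol(e) == 6)
  dd <- (e[, 1] - e[, 2])^2 + (e[, 2] - e[, 3])^2 + (e[, 1] - e[, 3])^2
  sh <- if (strict) 6 * (e[, 4] + e[, 5] + e[, 6])
        else 6 * (e[, 4]^2 + e[, 5]^2 + e[, 6]^2)
  (2 / 3) * sqrt(pmax(dd + sh, 0))
}

#' Prendergast mechanoregulation stimulus
#'
#' Scalar differentiation stimulus combining octahedral shear strain and
#' interstitial fluid velocity,
#' \deqn{S = \gamma / 0.0375 + \upsilon / 3\,\mu m\,s^{-1},}
#' which partitions the mechanical environment into the tissue fates of
#' [differentiation_ranges()].
#'
#' @param gamma Octahedral shear strain (dimensionless, `>= 0`).
#' @param upsilon Interstitial fluid speed (um/s, `>= 0`).
#' @param a Strain denominator (dimensionless).
#' @param b Fluid-velocity denominator (um/s).
#' @return Stimulus `S >= 0`.
#' @export
#' @examples
#' prendergast_stimulus(0.0375, 3)  # 2
prendergast_stimulus <- function(gamma, upsilon, a = 0.0375, b = 3) {
  if (any(gamma < 0) || any(upsilon < 0))
    stop("prendergast_stimulus: gamma and upsilon must be non-negative",
         call. = FALSE)
  gamma / a + upsilon / b
}

#' MSC differentiation ranges
#'
#' The stimulus axis is partitioned into the differentiation fates:
#' `S <= 2.53` mature osteoblast, `2.53 < S <= 3.00` immature osteoblast,
#' `3.00 < S <= 5.00` chondrocyte, `S > 5.00` fibroblast. Upper bounds are
#' inclusive.
#'
#' @param osteoblast_mature Upper bound of the mature-osteoblast range.
#' @param osteoblast Upper bound of the (immature) osteoblast range.
#' @param chondrocyte Upper bound of the chondrocyte range.
#' @return A named list of the three boundaries, class `differentiation_ranges`.
#' @export
differentiation_ranges <- function(osteoblast_mature = 2.53,
                                   osteoblast = 3.00,
                                   chondrocyte = 5.00) {
  if (!(osteoblast_mature < osteoblast && osteoblast < chondrocyte))
    stop("differentiation_ranges: boundaries must be strictly increasing",
         call. = FALSE)
  r <- list(osteoblast_mature = osteoblast_mature, osteoblast = osteoblast,
            chondrocyte = chondrocyte)
  class(r) <- "differentiation_ranges"
  r
}

# Fate from stimulus: returns list(phenotype code, mature flag).
fate_from_stimulus <- function(s, ranges = differentiation_ranges()) {
  pheno <- ifelse(s <= ranges$osteoblast, PHENO_OSTEOBLAST,
           ifelse(s <= ranges$chondrocyte, PHENO_CHONDROCYTE, PHENO_FIBROBLAST))
  list(phenotype = as.integer(pheno), mature = s <= ranges$osteoblast_mature)
}
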