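#' Young's modulus from the thin-plate relation
#'
#' Inverts the thin-plate formula `k_c = E d^3 / (12 (1 - nu^2))` relating
#' the bending rigidity of a thin isotropic plate to its Young's modulus,
#' Poisson's ratio and thickness:
#' `E = 12 k_c (1 - nu^2) / d^3`.
#'
#' @param k_c Bending rigidity (epsilon); must be positive.
#' @param nu Poisson's ratio (dimensionless); `|nu| < 1`.
#' @param d Membrane thickness (sigma_LJ); must be positive.
#' @return Young's modulus in epsilon / sigma_LJ^3.
#' @export
#' @examples
#' young_modulus(5.2, 0.50, 5.48)   # ~0.28, fluid bilayer
#' young_modulus(7.6, 0.40, 4.86)   # ~0.67, interdigitated bilayer
young_modulus <- function(k_c, nu, d) {
  if (any(d <= 0)) stop("thickness d must be positive")
  if (any(abs(nu) >= 1)) stop("|nu| must be < 1")
  if (any(k_c <= 0)) stop("bending rigidity k_c must be positive")
  12 * k_c * (1 - nu^2) / d^3
}

#' Assemble the elastic-constant report of one phase
#'
#' Combines a spectrum fit (bending rigidity), the Poisson-protocol results
#' for strains along both lateral axes, and the membrane descriptors into
#' a per-phase elastic-moduli summary.  In-plane isotropy is accepted when
#' `|nu_xy - nu_yx| <= iso_factor * sqrt(se_xy^2 + se_yx^2)`; only for an
#' isotropic membrane is the thin-plate relation applicable, so the
#' Young's modulus is withheld (NA) for anisotropic phases such as the
#' gel.  When computed, E uses the mean of `nu_xy` and `nu_yx`.
#'
#' @param spectrum A [fit_helfrich()] result.
#' @param poisson A single [measure_poisson()] result (isotropy then
#'   untestable, treated as declared-isotropic only if
#'   `assume_isotropic = TRUE`) or a list of two results with strains along
#'   different axes.
#' @param descriptors A [membrane_descriptors()] result; supplies the
#'   thickness entering the thin-plate relation.
#' @param iso_factor Stderr multiple for the isotropy test (default 2).
#' @param assume_isotropic Declare isotropy when only one strain direction
#'   was measured.
#' @return An object of class `elastic_moduli`.
#' @export
phase_report <- function(spectrum, poisson, descriptors, iso_factor = 2,
                         assume_isotropic = FALSE) {
  if (is.null(spectrum) || is.null(poisson) || is.null(descriptors)) {
    missing <- c("spectrum", "poisson", "descriptors")[
      c(is.null(spectrum), is.null(poisson), is.null(descriptors))]
    stop("missing inputs: ", paste(missing, collapse = ", "))
  }
  if (!isTRUE(spectrum$ok)) stop("spectrum fit failed (k_c <= 0)")
  if (inherits(poisson, "poisson_result")) poisson <- list(poisson)
  get_nu <- function(pair) {
    for (p in poisson) {
      row <- p$nu[p$nu$pair == pair, , drop = FALSE]
      if (nrow(row) == 1) return(row)
    }
    NULL
  }
  nxy <- get_nu("nu_xy")
  nyx <- get_nu("nu_yx")
  d <- descriptors$thickness

  if (!is.null(nxy) && !is.null(nyx)) {
    se <- sqrt(nxy$stderr^2 + nyx$stderr^2)
    isotropic <- abs(nxy$estimate - nyx$estimate) <= iso_factor * se
    nu <- mean(c(nxy$estimate, nyx$estimate))
  } else {
    one <- if (!is.null(nxy)) nxy else nyx
    if (is.null(one)) stop("poisson results carry no in-plane nu estimate")
    isotropic <- if (assume_isotropic) TRUE else NA
    nu <- one$estimate
  }
  E <- if (isTRUE(isotropic)) young_modulus(spectrum$k_c, nu, d) else NA_real_
  structure(list(
    k_c = spectrum$k_c, k_c_se = spectrum$k_c_se,
    nu_xy = if (is.null(nxy)) NA_real_ else nxy$estimate,
    nu_yx = if (is.null(nyx)) NA_real_ else nyx$estimate,
    nu = nu, d = d, E = E, isotropic = isotropic),
    class = "elastic_moduli")
}

#' @export
print.elastic_moduli <- function(x, ...) {
  cat(sprintf("<elastic_moduli> k_c = %.3f epsilon, d = %.3f sigma_LJ\n",
              x$k_c, x$d))
  cat(sprintf("  nu_xy = %.3f, nu_yx = %.3f -> %s\n", x$nu_xy, x$nu_yx,
              if (isTRUE(x$isotropic)) "isotropic"
              else if (isFALSE(x$isotropic)) "anisotropic"
              else "isotropy untested"))
  if (is.na(x$E)) {
    cat("  E withheld (thin-plate relation needs in-plane isotropy)\n")
  } else {
    cat(sprintf("  E = %.3f epsilon/sigma_LJ^3 (nu = %.3f)\n", x$E, x$nu))
  }
  invisible(x)
}
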