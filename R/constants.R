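#' Physical constants used by the Eyring machinery
#'
#' Fixed CODATA 2018 values for the Boltzmann and Planck constants and the
#' molar gas constant in kcal/(mol K), together with the default assay
#' temperature of 310.15 K (37 degrees C, the temperature of the GSH
#' kinetic experiments).
#'
#' @return A named list with elements `k_B` (J/K), `h` (J s), `R`
#'   (kcal/(mol K)) and `T_default` (K).
#' @examples
#' crg_constants()$T_default
#' @export
crg_constants <- function() {
  list(
    k_B = 1.380649e-23,      # J/K, exact (SI 2019)
    h = 6.62607015e-34,      # J s, exact (SI 2019)
    R = 1.987204e-3,         # kcal/(mol K)
    T_default = 310.15       # K
  )
}

#' Free-energy cost of GSH deprotonation at assay pH
#'
#' Thiolate-anion transition-state calculations sit below experimental
#' barriers because glutathione is almost entirely protonated at pH 7.4;
#' deprotonation to the reactive thiolate is endergonic by about
#' 3.1 kcal/mol under the assay conditions. Adding this constant to a
#' thiolate-referenced computed barrier puts it on the experimental scale.
#'
#' @return Numeric scalar, kcal/mol.
#' @export
gsh_deprotonation_penalty <- function() 3.1

.assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
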