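#' Registered descriptor vocabulary
#'
#' The electronic and steric descriptors the screening step knows about,
#' with their units. Descriptor columns outside this vocabulary are
#' ignored by [screen_descriptors()] unless registered here.
#'
#' @return A data.frame with columns `name` and `unit`.
#' @export
descriptor_vocabulary <- function() {
  data.frame(
    name = c("EA_eV", "LUMO_eV", "lumo_coef_Cbeta", "lumo_coef_Calpha",
             "npa_Cbeta", "c13_Cbeta_ppm", "h1_Hbeta1_ppm", "dihedral_deg",
             "nics0zz_ppm", "nics1zz_ppm", "sigma_het", "e_CT",
             "cs_distance_A", "EA_protonated_eV"),
    unit = c("eV", "eV", "dimensionless", "dimensionless",
             "e", "ppm", "ppm", "degrees",
             "ppm", "ppm", "dimensionless", "e",
             "Angstrom", "eV"),
    stringsAsFactors = FALSE)
}

#' Hammett-type substituent constant for a heteroaryl group
#'
#' Defined as the difference between the aqueous pKa of benzoic acid
#' (the reference) and that of the heteroaryl carboxylic acid, under the
#' same (computational) protocol:
#' `sigma_Het = pKa(Ph) - pKa(Het)`, with implicit reaction constant
#' rho = 1 for the benzoic-acid ionization reference, as in the classical
#' Hammett definition. A more acidic heteroaryl acid (lower pKa) gives a
#' positive value, i.e. an electron-withdrawing heteroarene; a negative
#' value marks a heteroarene more electron-donating than phenyl.
#'
#' @param pka_het pKa of the heteroaryl carboxylic acid.
#' @param pka_ref pKa of benzoic acid under the same protocol
#'   (default 4.20, the experimental aqueous value).
#' @return Dimensionless substituent constant (vectorized over `pka_het`).
#' @examples
#' sigma_het(3.2)  # stronger acid than benzoic -> electron-withdrawing
#' @export
sigma_het <- function(pka_het, pka_ref = 4.20) {
  if (!is.numeric(pka_het) || any(!is.finite(pka_het))) {
    stop("`pka_het` must be finite", call. = FALSE)
  }
  if (!is.numeric(pka_ref) || any(!is.finite(pka_ref))) {
    stop("`pka_ref` must be finite", call. = FALSE)
  }
  pka_ref - pka_het
}

#' Protonated fraction of an ionizable group (Henderson-Hasselbalch)
#'
#' @param pka pKa of the conjugate acid.
#' @param ph Solution pH (default 7.4, the assay buffer).
#' @return Fraction protonated in (0, 1): `1 / (1 + 10^(ph - pka))`.
#' @examples
#' protonated_fraction(7.4, 7.4)  # 0.5
#' @export
protonated_fraction <- function(pka, ph = 7.4) {
  if (!is.numeric(pka) || !is.numeric(ph)) {
    stop("`pka` and `ph` must be numeric", call. = FALSE)
  }
  1 / (1 + 10^(ph - pka))
}

#' Protonation-state-weighted barrier prediction
#'
#' For compounds with a basic ring nitrogen in appreciable acid-base
#' equilibrium at assay pH, a predicted barrier is computed for both the
#' protonated and unprotonated species and combined with the protonated
#' fraction `f`. Two conventions are offered: a weighted mean of the two
#' free energies (`dg_space`, the default) or a weighted mean of the two
#' Eyring rates converted back to a free energy (`rate_space`). By
#' convexity of the exponential, the rate-space result never exceeds the
#' free-energy-space result, and both lie between the two inputs.
#'
#' @param dg_prot Predicted barrier for the protonated species, kcal/mol.
#' @param dg_unprot Predicted barrier for the unprotonated species, kcal/mol.
#' @param f_prot Protonated fraction in `[0, 1]`; see
#'   [protonated_fraction()].
#' @param mode `"dg_space"` (default) or `"rate_space"`.
#' @param temperature Kelvin, used only in rate space.
#' @return Weighted predicted barrier, kcal/mol.
#' @export
weighted_prediction <- function(dg_prot, dg_unprot, f_prot,
                                mode = c("dg_space", "rate_space"),
                                temperature = crg_constants()$T_default) {
  mode <- match.arg(mode)
  if (any(f_prot < 0 | f_prot > 1)) {
    stop("`f_prot` must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "dg_space") {
    f_prot * dg_prot + (1 - f_prot) * dg_unprot
  } else {
    k <- f_prot * dg_to_rate(dg_prot, temperature) +
      (1 - f_prot) * dg_to_rate(dg_unprot, temperature)
    rate_to_dg(k, temperature)
  }
}

#' Read a compound descriptor table from CSV
#'
#' Expected columns include `compound_id` (mandatory), optionally
#' `heteroaryl_name`, the registered descriptor columns (see
#' [descriptor_vocabulary()]), measured kinetics (`t_half_min`,
#' `k_per_s`, `dG_exp_kcal_mol`), `dG_dft_kcal_mol`, `pKa_conjugate_acid`,
#' `outlier`, `outlier_reason`, and `provenance`.
#' Derived columns are filled in when absent: `k_per_s` from `t_half_min`,
#' `dG_exp_kcal_mol` from `k_per_s`, and `log_k_gsh` (log10 of k in 1/s).
#'
#' @param path CSV file path.
#' @param temperature Kelvin for the Eyring conversion.
#' @return A data.frame of class `descriptor_table`.
#' @export
read_descriptor_csv <- function(path, temperature = crg_constants()$T_default) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_descriptor_table(df, temperature = temperature)
}

#' Coerce a data.frame to a descriptor table, deriving kinetic columns
#'
#' @param df A data.frame with at least `compound_id`.
#' @param temperature Kelvin.
#' @return The data.frame with derived columns `k_per_s`,
#'   `dG_exp_kcal_mol` and `log_k_gsh` populated where computable, classed
#'   as `descriptor_table`.
#' @export
as_descriptor_table <- function(df, temperature = crg_constants()$T_default) {
  if (!"compound_id" %in% names(df)) {
    stop("descriptor table needs a `compound_id` column", call. = FALSE)
  }
  if (anyDuplicated(df$compound_id)) {
    stop("duplicated compound_id in descriptor table", call. = FALSE)
  }
  if (!"k_per_s" %in% names(df)) df$k_per_s <- NA_real_
  if ("t_half_min" %in% names(df)) {
    fill <- is.na(df$k_per_s) & !is.na(df$t_half_min) & df$t_half_min > 0
    df$k_per_s[fill] <- log(2) / (df$t_half_min[fill] * 60)
  }
  if (!"dG_exp_kcal_mol" %in% names(df)) df$dG_exp_kcal_mol <- NA_real_
  fill <- is.na(df$dG_exp_kcal_mol) & !is.na(df$k_per_s) & df$k_per_s > 0
  df$dG_exp_kcal_mol[fill] <- rate_to_dg(df$k_per_s[fill], temperature)
  df$log_k_gsh <- ifelse(!is.na(df$k_per_s) & df$k_per_s > 0,
                         log10(df$k_per_s), NA_real_)
  if (!"outlier" %in% names(df)) df$outlier <- FALSE
  df$outlier <- as.logical(df$outlier)
  class(df) <- unique(c("descriptor_table", class(df)))
  df
}

#' Write a descriptor table to CSV
#'
#' Numeric columns round-trip at full double precision (up to 15
#' significant digits).
#'
#' @param table A descriptor table (data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(table, path) {
  out <- as.data.frame(table)
  class(out) <- "data.frame"
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}
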