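# residue masses (u), peptide-bonded (monomer minus water)
.residue_mass <- c(GLY = 57.05, ALA = 71.08, SER = 87.08, PRO = 97.12,
                   VAL = 99.13, THR = 101.10, CYS = 103.14, LEU = 113.16,
                   ILE = 113.16, ASN = 114.10, ASP = 115.09, GLN = 128.13,
                   LYS = 128.17, GLU = 129.12, MET = 131.19, HIS = 137.14,
                   PHE = 147.18, ARG = 156.19, TYR = 163.18, TRP = 186.21)

.N_AVOGADRO <- 6.02214076e23

#' Sequence molecular weight of a structure
#'
#' Sums standard residue masses over unique (chain, residue) protein
#' entries, plus one water per chain.
#'
#' @param structure a `structure_model`
#' @return Mass in kDa.
#' @export
sequence_mw <- function(structure) {
  a <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  key <- !duplicated(paste(a$chain, a$resno))
  res <- a$resname[key]
  m <- .residue_mass[res]
  if (any(is.na(m))) {
    warning("non-standard residue(s) ", paste(unique(res[is.na(m)]), collapse = ", "),
            " counted with the mean residue mass")
    m[is.na(m)] <- mean(.residue_mass)
  }
  (sum(m) + 18.02 * length(unique(a$chain))) / 1e3
}

#' Contrast-and-composition summary of a structure
#'
#' Total excess scattering length, mass, and excess scattering length per
#' unit mass under a contrast model; the ingredients of the I(0)-based
#' molecular weight estimate.
#'
#' @param structure a `structure_model`
#' @param contrast a [contrast_model()]
#' @return List: `sum_b_fm` (total excess scattering length, fm), `mass_kda`,
#'   `drho_m_cm_per_g` (excess scattering length per mass, cm/g).
#' @export
contrast_summary <- function(structure, contrast = contrast_model()) {
  db <- atom_weights(structure, contrast)
  mass_kda <- sequence_mw(structure)
  sum_b_cm <- sum(db) * 1e-13              # fm -> cm
  mass_g <- mass_kda * 1e3 / .N_AVOGADRO   # grams per particle
  list(sum_b_fm = sum(db), mass_kda = mass_kda,
       drho_m_cm_per_g = sum_b_cm / mass_g)
}

#' Molecular weight from forward scattering
#'
#' For data on absolute scale (cm^-1), \eqn{I(0) = c M (\Delta b_m)^2 / N_A}
#' with concentration `c` in g/cm^3 and the excess scattering length per
#' unit mass \eqn{\Delta b_m} in cm/g, so
#' \deqn{M = I(0) N_A / (c \, \Delta b_m^2).}
#'
#' @param i0 forward scattering, cm^-1 (absolute scale)
#' @param concentration_mg_ml protein concentration, mg/mL
#' @param drho_m_cm_per_g excess scattering length per unit mass under the
#'   measurement contrast (cm/g), e.g. from [contrast_summary()]
#' @return Estimated molecular weight in kDa.
#' @export
molecular_weight_from_i0 <- function(i0, concentration_mg_ml, drho_m_cm_per_g) {
  stopifnot(i0 > 0, concentration_mg_ml > 0)
  if (drho_m_cm_per_g == 0) stop("zero contrast: molecular weight undefined")
  c_g_cm3 <- concentration_mg_ml * 1e-3
  mw_g_mol <- i0 * .N_AVOGADRO / (c_g_cm3 * drho_m_cm_per_g^2)
  mw_g_mol / 1e3
}
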