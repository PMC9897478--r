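# Coherent neutron scattering lengths, fm (Sears compilation)
.b_coh_fm <- c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803,
               S = 2.847, P = 5.13, "NA" = 3.63, CL = 9.5770, K = 3.67,
               CA = 4.70, MG = 5.375, ZN = 5.680, FE = 9.45, SE = 7.970)

# Displaced atomic volumes, A^3 (Fraser-Traub-style group volumes for the
# organic elements; ionic crystal radii volumes for common counterions)
.vol_a3 <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, S = 19.86, P = 5.73,
             "NA" = 4.9, CL = 24.8, K = 11.0, CA = 7.9, MG = 2.4,
             ZN = 4.2, FE = 4.2, SE = 28.7)

.V_WATER <- 29.9  # A^3 per water molecule

# Per-residue heavy-atom hydrogen templates: for each side-chain atom name,
# total attached H and whether they are labile (N/O/S-bound). Backbone is
# handled uniformly (N-H labile, except proline; CA has 1 H, glycine 2).
# Asp/Glu carboxylates and the C-terminal carboxylate are taken deprotonated
# (neutral-pH solution); His as the neutral single N-H tautomer.
.sidechain_h <- list(
  ALA = list(CB = c(3, 0)),
  ARG = list(CB = c(2, 0), CG = c(2, 0), CD = c(2, 0), NE = c(1, 1),
             CZ = c(0, 0), NH1 = c(2, 2), NH2 = c(2, 2)),
  ASN = list(CB = c(2, 0), CG = c(0, 0), OD1 = c(0, 0), ND2 = c(2, 2)),
  ASP = list(CB = c(2, 0), CG = c(0, 0), OD1 = c(0, 0), OD2 = c(0, 0)),
  CYS = list(CB = c(2, 0), SG = c(1, 1)),
  GLN = list(CB = c(2, 0), CG = c(2, 0), CD = c(0, 0), OE1 = c(0, 0),
             NE2 = c(2, 2)),
  GLU = list(CB = c(2, 0), CG = c(2, 0), CD = c(0, 0), OE1 = c(0, 0),
             OE2 = c(0, 0)),
  GLY = list(),
  HIS = list(CB = c(2, 0), CG = c(0, 0), ND1 = c(1, 1), CD2 = c(1, 0),
             CE1 = c(1, 0), NE2 = c(0, 0)),
  ILE = list(CB = c(1, 0), CG1 = c(2, 0), CG2 = c(3, 0), CD1 = c(3, 0)),
  LEU = list(CB = c(2, 0), CG = c(1, 0), CD1 = c(3, 0), CD2 = c(3, 0)),
  LYS = list(CB = c(2, 0), CG = c(2, 0), CD = c(2, 0), CE = c(2, 0),
             NZ = c(3, 3)),
  MET = list(CB = c(2, 0), CG = c(2, 0), SD = c(0, 0), CE = c(3, 0)),
  PHE = list(CB = c(2, 0), CG = c(0, 0), CD1 = c(1, 0), CD2 = c(1, 0),
             CE1 = c(1, 0), CE2 = c(1, 0), CZ = c(1, 0)),
  PRO = list(CB = c(2, 0), CG = c(2, 0), CD = c(2, 0)),
  SER = list(CB = c(2, 0), OG = c(1, 1)),
  THR = list(CB = c(1, 0), OG1 = c(1, 1), CG2 = c(3, 0)),
  TRP = list(CB = c(2, 0), CG = c(0, 0), CD1 = c(1, 0), CD2 = c(0, 0),
             NE1 = c(1, 1), CE2 = c(0, 0), CE3 = c(1, 0), CZ2 = c(1, 0),
             CZ3 = c(1, 0), CH2 = c(1, 0)),
  TYR = list(CB = c(2, 0), CG = c(0, 0), CD1 = c(1, 0), CD2 = c(1, 0),
             CE1 = c(1, 0), CE2 = c(1, 0), CZ = c(0, 0), OH = c(1, 1)),
  VAL = list(CB = c(1, 0), CG1 = c(3, 0), CG2 = c(3, 0)))

#' Labile hydrogens per residue type
#'
#' Counts of exchangeable (N/O/S-bound) hydrogens per standard amino acid,
#' split into backbone (the amide H) and side chain.
#'
#' @return data.frame with columns `resname`, `backbone`, `sidechain`.
#' @export
labile_h_table <- function() {
  res <- names(.sidechain_h)
  side <- vapply(.sidechain_h, function(tpl)
    sum(vapply(tpl, `[`, 0, 2)), 0)
  data.frame(resname = res,
             backbone = ifelse(res == "PRO", 0L, 1L),
             sidechain = as.integer(side), row.names = NULL)
}

#' Neutron contrast model
#'
#' Describes the solvent and exchange conditions under which excess
#' scattering lengths are computed: the D2O fraction of the buffer, the
#' fraction of solvent-exposed labile hydrogens that have exchanged to
#' deuterium, and a shielded (transmembrane) selection whose labile
#' hydrogens are kept as 1H. The matched-out deuterated detergent belt is
#' taken as invisible (zero excess contrast).
#'
#' @param d2o_fraction solvent D2O fraction in `[0, 1]` (default 1).
#' @param exchanged_fraction fraction of non-shielded labile H exchanged
#'   (default 0.90, the expected extent after ~100 min at pH 7.5).
#' @param shielded_selection selection string for the membrane-shielded
#'   region, or `NULL` (none).
#' @param b_table,volume_table named vectors overriding the built-in
#'   scattering-length (fm) and displaced-volume (A^3) tables.
#' @return Object of class `contrast_model`.
#' @export
contrast_model <- function(d2o_fraction = 1, exchanged_fraction = 0.90,
                           shielded_selection = NULL,
                           b_table = .b_coh_fm, volume_table = .vol_a3) {
  stopifnot(d2o_fraction >= 0, d2o_fraction <= 1,
            exchanged_fraction >= 0, exchanged_fraction <= 1)
  structure(list(d2o_fraction = d2o_fraction,
                 exchanged_fraction = exchanged_fraction,
                 shielded_selection = shielded_selection,
                 b_table = b_table, volume_table = volume_table),
            class = "contrast_model")
}

#' Solvent scattering length density
#' @param contrast a [contrast_model()]
#' @return fm per cubic Angstrom.
#' @export
solvent_sld <- function(contrast) {
  b <- contrast$b_table
  b_h2o <- 2 * b[["H"]] + b[["O"]]
  b_d2o <- 2 * b[["D"]] + b[["O"]]
  (contrast$d2o_fraction * b_d2o + (1 - contrast$d2o_fraction) * b_h2o) / .V_WATER
}

#' Per-atom hydrogen composition under an exchange model
#'
#' Partitions the hydrogens attached to each heavy atom into effective 1H
#' and D counts: carbon-bound H never exchange; labile H in the shielded
#' selection stay 1H; the rest exchange with probability
#' `exchanged_fraction` into the solvent isotope mix.
#'
#' @param structure a `structure_model`
#' @param contrast a [contrast_model()]
#' @return data.frame with per-atom columns `n_h_total`, `n_h_labile`,
#'   `n_h_eff` (effective protium count) and `n_d_eff` (effective deuterium
#'   count); fractional values are expected.
#' @export
labile_hydrogen_count <- function(structure, contrast = contrast_model()) {
  a <- structure$atoms
  n <- nrow(a)
  n_tot <- numeric(n); n_lab <- numeric(n)
  known <- a$resname %in% names(.sidechain_h)
  if (any(!known & !a$is_hetero)) {
    warning("unknown residue(s) ", paste(setdiff(unique(a$resname[!known & !a$is_hetero]),
                                                 ""), collapse = ", "),
            ": contributing zero labile hydrogens")
  }
  for (i in which(known)) {
    nm <- a$name[i]
    if (nm == "N") {
      if (a$resname[i] != "PRO") { n_tot[i] <- 1; n_lab[i] <- 1 }
    } else if (nm == "CA") {
      n_tot[i] <- if (a$resname[i] == "GLY") 2 else 1
    } else if (!nm %in% c("C", "O", "OXT")) {
      tpl <- .sidechain_h[[a$resname[i]]][[nm]]
      if (!is.null(tpl)) { n_tot[i] <- tpl[1]; n_lab[i] <- tpl[2] }
    }
  }
  shielded <- rep(FALSE, n)
  if (!is.null(contrast$shielded_selection))
    shielded[select_atoms(structure, contrast$shielded_selection)] <- TRUE
  x <- contrast$d2o_fraction * contrast$exchanged_fraction
  n_d <- ifelse(shielded, 0, n_lab * x)
  data.frame(n_h_total = n_tot, n_h_labile = n_lab,
             n_h_eff = n_tot - n_d, n_d_eff = n_d)
}

#' Per-atom excess neutron scattering lengths
#'
#' For each heavy atom `i` (hydrogens implicit via residue templates):
#' \deqn{\Delta b_i = b_i + n_H b_H + n_D b_D - \rho_{solv} v_i}
#' where `v_i` is the displaced volume of the atom plus its attached
#' hydrogens and `rho_solv` is the solvent scattering length density.
#'
#' @inheritParams labile_hydrogen_count
#' @return Numeric vector of excess scattering lengths (fm), one per atom.
#' @export
excess_scattering_lengths <- function(structure, contrast = contrast_model()) {
  a <- structure$atoms
  b <- contrast$b_table
  vol <- contrast$volume_table
  b_heavy <- unname(b[a$element]); b_heavy[is.na(b_heavy)] <- 0
  v_heavy <- unname(vol[a$element])
  if (any(is.na(v_heavy))) {
    # element absent from the volume table: fall back to carbon-like volume
    warning("no displaced volume for element(s) ",
            paste(unique(a$element[is.na(v_heavy)]), collapse = ", "),
            "; using carbon volume")
    v_heavy[is.na(v_heavy)] <- vol[["C"]]
  }
  hc <- labile_hydrogen_count(structure, contrast)
  v_tot <- v_heavy + hc$n_h_total * vol[["H"]]
  b_heavy + hc$n_h_eff * b[["H"]] + hc$n_d_eff * b[["D"]] -
    solvent_sld(contrast) * v_tot
}

#' Per-atom scattering weights for a structure
#'
#' Dispatch helper used by all scattering operations: explicit per-atom
#' weights (toy pseudo-atom models carry a `b` column) win when no contrast
#' model is supplied; otherwise weights come from
#' [excess_scattering_lengths()].
#'
#' @inheritParams labile_hydrogen_count
#' @param contrast a [contrast_model()] or `NULL`
#' @return Numeric vector of per-atom weights (fm).
#' @export
atom_weights <- function(structure, contrast = NULL) {
  if (is.null(contrast)) {
    if (!is.null(structure$atoms$b)) return(structure$atoms$b)
    contrast <- contrast_model()
  }
  excess_scattering_lengths(structure, contrast)
}
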