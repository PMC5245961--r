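AVOGADRO <- 6.02214076e23

#' Round an origin or molecule count the way it is reported
#'
#' Counts of 10,000 or more are rounded to the nearest thousand (half away
#' from zero), smaller counts to the nearest integer, mirroring the "~"
#' precision with which genome-wide origin numbers are quoted. Raw values
#' are always retained alongside in [quant_report()].
#'
#' @param x Numeric count.
#' @return Rounded count.
#' @export
round_count <- function(x) {
  ifelse(abs(x) >= 1e4, floor(x / 1000 + 0.5) * 1000, round(x))
}

#' Molecules in a protein band of known mass
#'
#' count = mass / molar mass x Avogadro's number, for a band on a
#' quantitative western matched against a dilution series of a recombinant
#' standard.
#'
#' @param mass_ng Band mass in ng.
#' @param molar_mass_kDa Molar mass of the standard in kDa.
#' @param report Round to 3 significant figures (the reporting precision);
#'   `FALSE` returns the raw value.
#' @return Molecule count.
#' @export
molecules_from_mass <- function(mass_ng, molar_mass_kDa, report = TRUE) {
  check_num(mass_ng, "mass_ng", lower = 1e-300)
  check_num(molar_mass_kDa, "molar_mass_kDa", lower = 1e-300)
  x <- mass_ng * 1e-9 / (molar_mass_kDa * 1000) * AVOGADRO
  if (report) signif(x, 3) else x
}

#' Band mass corresponding to a molecule count
#'
#' Inverse of [molecules_from_mass()].
#'
#' @param n_molecules Molecule count.
#' @param molar_mass_kDa Molar mass in kDa.
#' @param report Round to 3 significant figures.
#' @return Mass in ng.
#' @export
mass_from_molecules <- function(n_molecules, molar_mass_kDa,
                                report = TRUE) {
  check_num(n_molecules, "n_molecules", lower = 1e-300)
  check_num(molar_mass_kDa, "molar_mass_kDa", lower = 1e-300)
  x <- n_molecules / AVOGADRO * (molar_mass_kDa * 1000) * 1e9
  if (report) signif(x, 3) else x
}

#' Molecules per cell
#'
#' @param total_molecules Molecule count in the loaded lysate.
#' @param cells_loaded Number of cells the lysate derives from.
#' @param report Round to 3 significant figures.
#' @return Per-cell molecule count.
#' @export
molecules_per_cell <- function(total_molecules, cells_loaded,
                               report = TRUE) {
  check_num(total_molecules, "total_molecules", lower = 0)
  check_num(cells_loaded, "cells_loaded", lower = 1e-300)
  x <- total_molecules / cells_loaded
  if (report) signif(x, 3) else x
}

#' Upper bound on undetected molecules per cell
#'
#' If a protein is undetectable on a blot whose smallest detectable signal
#' is `detection_fraction` of the wild-type signal, the knockout can carry
#' at most `per_cell x detection_fraction` molecules per cell.
#'
#' @param per_cell Wild-type molecules per cell.
#' @param detection_fraction Smallest detectable fraction of the wild-type
#'   signal, in (0, 1].
#' @return Maximum undetected molecules per cell.
#' @export
detection_upper_bound <- function(per_cell, detection_fraction) {
  check_num(per_cell, "per_cell", lower = 0)
  check_num(detection_fraction, "detection_fraction", lower = 1e-300,
            upper = 1)
  per_cell * detection_fraction
}

#' Genome-wide origin number from a combing inter-origin distance
#'
#' origins = genome size / median inter-origin distance; reported to the
#' nearest thousand for counts of 10,000 or more (see [round_count()]).
#'
#' @param genome_bp Total DNA content in bp (e.g. 6e9 for a near-diploid
#'   human cell).
#' @param median_iod_bp Median single-molecule inter-origin distance in bp.
#' @param report Apply [round_count()].
#' @return Origin count.
#' @export
origins_from_combing <- function(genome_bp, median_iod_bp, report = TRUE) {
  check_num(genome_bp, "genome_bp", lower = 1e-300)
  check_num(median_iod_bp, "median_iod_bp", lower = 1e-300)
  x <- genome_bp / median_iod_bp
  if (report) round_count(x) else x
}

#' Genome-wide origin number extrapolated from uniquely mapped peaks
#'
#' Scales the number of peaks mapped to unique sequence up by ploidy and
#' down by the uniquely mappable fraction of the genome:
#' origins = n_unique x ploidy / unique_mappable_fraction.
#'
#' @param n_unique Peaks mapped to unique DNA sequence.
#' @param ploidy Genome copies per cell.
#' @param unique_mappable_fraction Fraction of the genome in which peaks
#'   can be uniquely mapped, in (0, 1].
#' @param report Apply [round_count()].
#' @return Origin count.
#' @export
origins_from_unique_peaks <- function(n_unique, ploidy = 2,
                                      unique_mappable_fraction = 0.5,
                                      report = TRUE) {
  check_num(n_unique, "n_unique", lower = 0)
  check_num(ploidy, "ploidy", lower = 1e-300)
  check_num(unique_mappable_fraction, "unique_mappable_fraction",
            lower = 1e-300, upper = 1)
  x <- n_unique * ploidy / unique_mappable_fraction
  if (report) round_count(x) else x
}

#' Helicase-loading burden per initiator territory
#'
#' How many helicase complexes a single initiator would have to load if
#' complexes sit `spacing_bp` apart across a `territory_bp` stretch of
#' chromatin: territory / spacing, rounded to the nearest integer.
#'
#' @param territory_bp Territory size in bp.
#' @param spacing_bp Spacing between loaded complexes in bp.
#' @param report Round to the nearest integer.
#' @return Complexes per territory.
#' @export
loading_burden <- function(territory_bp, spacing_bp, report = TRUE) {
  check_num(territory_bp, "territory_bp", lower = 1e-300)
  check_num(spacing_bp, "spacing_bp", lower = 1e-300)
  x <- territory_bp / spacing_bp
  if (report) round(x) else x
}

#' Licensing-arithmetic report
#'
#' Runs the whole quantification chain on one set of named inputs and
#' returns raw and reported values with the formula used per row: molecules
#' in the matched standard band, molecules per cell, the detection-limit
#' upper bound for the knockout, genome-wide origin numbers from combing
#' and from unique-peak extrapolation, and the per-territory loading
#' burden.
#'
#' @param band_mass_ng Standard band mass matched to the lysate signal, ng.
#' @param molar_mass_kDa Molar mass of the standard, kDa.
#' @param cells_loaded Cells in the matched lysate lane.
#' @param detection_fraction Smallest detectable fraction of the wild-type
#'   signal.
#' @param genome_bp Total DNA content, bp.
#' @param median_iod_bp Median combing inter-origin distance, bp.
#' @param n_unique_peaks Peaks mapped to unique sequence.
#' @param ploidy Genome copies per cell.
#' @param unique_mappable_fraction Uniquely mappable genome fraction.
#' @param territory_bp Initiator territory size, bp.
#' @param spacing_bp Loaded-complex spacing, bp.
#'
#' @return Data frame with columns `quantity`, `raw`, `reported`,
#'   `formula`.
#' @export
quant_report <- function(band_mass_ng = 2.54, molar_mass_kDa = 100,
                         cells_loaded = 1e5, detection_fraction = 0.01,
                         genome_bp = 6e9, median_iod_bp = 115500,
                         n_unique_peaks = 13000, ploidy = 2,
                         unique_mappable_fraction = 0.5,
                         territory_bp = 3.5e6, spacing_bp = 1e5) {
  total_raw <- molecules_from_mass(band_mass_ng, molar_mass_kDa,
                                   report = FALSE)
  per_cell_raw <- molecules_per_cell(total_raw, cells_loaded,
                                     report = FALSE)
  per_cell <- signif(per_cell_raw, 3)
  bound_raw <- detection_upper_bound(per_cell, detection_fraction)
  comb_raw <- origins_from_combing(genome_bp, median_iod_bp, report = FALSE)
  uniq_raw <- origins_from_unique_peaks(n_unique_peaks, ploidy,
                                        unique_mappable_fraction,
                                        report = FALSE)
  burden_raw <- loading_burden(territory_bp, spacing_bp, report = FALSE)
  data.frame(
    quantity = c("molecules_in_band", "molecules_per_cell",
                 "detection_upper_bound_per_cell", "origins_from_combing",
                 "origins_from_unique_peaks", "loading_burden"),
    raw = c(total_raw, per_cell_raw, bound_raw, comb_raw, uniq_raw,
            burden_raw),
    reported = c(signif(total_raw, 3), per_cell, bound_raw,
                 round_count(comb_raw), round_count(uniq_raw),
                 round(burden_raw)),
    formula = c(
      "mass_ng / (molar_mass_kDa * 1000) * N_A * 1e-9",
      "molecules_in_band / cells_loaded",
      "molecules_per_cell * detection_fraction",
      "genome_bp / median_iod_bp",
      "n_unique_peaks * ploidy / unique_mappable_fraction",
      "territory_bp / spacing_bp"),
    stringsAsFactors = FALSE)
}
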