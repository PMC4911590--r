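# Protein statistics: molecular weight and isoelectric point.

# Average (isotope-averaged) residue masses in daltons, i.e. amino-acid mass
# minus one water. Values as used by the common web MW calculators.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Bjellqvist-style pKa values (the set behind the ExPASy pI tool): the two
# termini plus the seven ionizable side chains.
PKA_TABLE <- c(
  Nterm = 7.50, Cterm = 3.55,
  D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
  H = 5.98, K = 10.00, R = 12.00
)

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that uppercases
#' sequences and keeps only the first whitespace-delimited token of each
#' header as the protein id.
#'
#' @param path Path to a (possibly gzipped) protein FASTA file.
#' @return A named character vector of uppercase amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

validate_sequence <- function(sequence, allow_x = TRUE) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single nonempty string", call. = FALSE)
  sequence <- toupper(sequence)
  letters <- strsplit(sequence, "")[[1]]
  allowed <- names(AA_RESIDUE_MASS)
  if (allow_x) allowed <- c(allowed, "X")
  bad <- setdiff(unique(letters), allowed)
  if (length(bad) > 0)
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  letters
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, i.e. the mass of the intact
#' polypeptide. `X` (unknown residue) contributes the mean of the twenty
#' canonical residue masses; any other non-canonical letter is an error.
#'
#' @param sequence Amino-acid sequence (single string, case-insensitive).
#' @return Molecular weight in kilodaltons (not rounded).
#' @examples
#' compute_mw("G")   # glycine: 75.07 Da = 0.07507 kD
#' @export
compute_mw <- function(sequence) {
  letters <- validate_sequence(sequence)
  masses <- AA_RESIDUE_MASS[letters]
  masses[letters == "X"] <- mean(AA_RESIDUE_MASS)
  (sum(masses) + WATER_MASS) / 1000
}

#' Henderson-Hasselbalch net charge of a protein at a given pH
#'
#' Positive contributions from the N-terminus, H, K and R; negative from the
#' C-terminus, D, E, C and Y. `X` residues carry no charge.
#'
#' @param sequence Amino-acid sequence.
#' @param ph pH value (may be a vector).
#' @param pka Named pKa table; defaults to the package's Bjellqvist-style set.
#' @return Net charge at each `ph`.
#' @export
net_charge <- function(sequence, ph, pka = PKA_TABLE) {
  letters <- validate_sequence(sequence)
  counts <- table(factor(letters, levels = c(names(AA_RESIDUE_MASS), "X")))
  pos_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - ph))
  charge <- pos_frac(pka[["Nterm"]]) + neg_frac(pka[["Cterm"]])
  for (res in c("H", "K", "R"))
    charge <- charge + counts[[res]] * pos_frac(pka[[res]])
  for (res in c("D", "E", "C", "Y"))
    charge <- charge + counts[[res]] * neg_frac(pka[[res]])
  unname(charge)
}

#' Protein isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge is zero. Net charge
#' is strictly decreasing in pH, so the root is unique; it is located by
#' bisection on \[0, 14\].
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance on pH (default 1e-4).
#' @return The isoelectric point (pH units).
#' @export
compute_pi <- function(sequence, pka = PKA_TABLE, tol = 1e-4) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-protein statistics table
#'
#' Computes length, molecular weight (kD) and isoelectric point for a set of
#' protein sequences, mirroring the columns of a family catalog table.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param digits Decimal places for the reported pI and MW (default 2,
#'   matching the precision such tables are usually printed at).
#' @return A data.frame with columns `id`, `length_aa`, `pi`, `mw_kd`.
#' @export
protein_stats <- function(proteins, digits = 2) {
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))
  data.frame(
    id = names(proteins),
    length_aa = nchar(proteins),
    pi = round(vapply(proteins, compute_pi, numeric(1)), digits),
    mw_kd = round(vapply(proteins, compute_mw, numeric(1)), digits),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
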