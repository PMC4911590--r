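# Domain scanning and family selection by domain co-occurrence.
#
# Family membership follows the classic two-domain rule: a protein belongs
# to the CIPK family iff it carries both a protein-kinase domain and the
# NAF domain. Real hmmscan output can be ingested (parse_domain_table); for
# synthetic data a position-specific scoring matrix (PSSM) scanner stands in
# for the profile-HMM search while preserving the co-occurrence logic.

# Fixed 20-mer consensus motifs for the two planted domains. These are
# package-defined stand-ins (kinase catalytic-loop-like and NAF-like), not
# Pfam models; only their co-occurrence matters downstream.
KINASE_CONSENSUS <- "HRDLKPENLLLDANGNLKIS"
NAF_CONSENSUS <- "NAFDLISLSEGFNLSPLFEE"

#' Build a log-odds PSSM from a consensus sequence
#'
#' Columns follow a consensus-heavy model: the consensus residue has
#' probability `match_prob` and the remaining probability is spread evenly
#' over the other 19 residues; the background is uniform (1/20). Scores are
#' per-position log2 odds. Non-canonical residues (e.g. `X`) score as a
#' mismatch.
#'
#' @param consensus Consensus amino-acid string.
#' @param label Domain label attached to hits (e.g. `"NAF"`).
#' @param match_prob Probability mass on the consensus residue per column.
#' @param threshold_frac Reporting threshold as a fraction of the maximum
#'   attainable score (default 0.5).
#' @return An object of class `pssm`.
#' @export
build_pssm <- function(consensus, label, match_prob = 0.6,
                       threshold_frac = 0.5) {
  stopifnot(match_prob > 0.05, match_prob < 1)
  letters <- strsplit(toupper(consensus), "")[[1]]
  aa <- names(AA_RESIDUE_MASS)
  stopifnot(all(letters %in% aa))
  w <- length(letters)
  match_lo <- log2(match_prob / 0.05)
  mismatch_lo <- log2(((1 - match_prob) / 19) / 0.05)
  mat <- matrix(mismatch_lo, nrow = 21, ncol = w,
                dimnames = list(c(aa, "X"), NULL))
  mat[cbind(match(letters, rownames(mat)), seq_len(w))] <- match_lo
  max_score <- match_lo * w
  structure(
    list(label = label, consensus = paste(letters, collapse = ""),
         matrix = mat, width = w, max_score = max_score,
         threshold = threshold_frac * max_score),
    class = "pssm"
  )
}

#' Default kinase + NAF stand-in PSSMs
#'
#' The two fixed motifs the synthetic generator plants in family members.
#'
#' @inheritParams build_pssm
#' @return Named list of two `pssm` objects (`Pkinase`, `NAF`).
#' @export
default_pssms <- function(match_prob = 0.6, threshold_frac = 0.5) {
  list(
    Pkinase = build_pssm(KINASE_CONSENSUS, "Pkinase", match_prob,
                         threshold_frac),
    NAF = build_pssm(NAF_CONSENSUS, "NAF", match_prob, threshold_frac)
  )
}

empty_hits <- function() {
  data.frame(protein_id = character(), domain_label = character(),
             ali_start = integer(), ali_end = integer(),
             bit_score = numeric(), e_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Scan a protein with one or more PSSMs
#'
#' For each PSSM the maximal-scoring window is reported when its score (sum
#' of per-position log-odds) reaches the PSSM's threshold. A sequence
#' shorter than a PSSM yields no hit for that PSSM.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param pssms List of `pssm` objects, e.g. [default_pssms()].
#' @param id Protein id recorded in the hits (default `"query"`).
#' @return A domain-hit data.frame (`protein_id`, `domain_label`,
#'   `ali_start`, `ali_end`, `bit_score`, `e_value`); `e_value` is `NA` in
#'   PSSM mode.
#' @export
scan_motifs <- function(sequence, pssms, id = "query") {
  letters <- validate_sequence(sequence)
  hits <- empty_hits()
  for (p in pssms) {
    stopifnot(inherits(p, "pssm"))
    n <- length(letters)
    if (n < p$width) next
    idx <- match(letters, rownames(p$matrix))
    # per-position log-odds for every window start, summed by convolution
    n_win <- n - p$width + 1L
    scores <- vapply(seq_len(n_win), function(s) {
      sum(p$matrix[cbind(idx[s:(s + p$width - 1L)], seq_len(p$width))])
    }, numeric(1))
    best <- which.max(scores)
    if (scores[best] >= p$threshold) {
      hits <- rbind(hits, data.frame(
        protein_id = id, domain_label = p$label,
        ali_start = best, ali_end = best + p$width - 1L,
        bit_score = scores[best], e_value = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
  }
  hits
}

#' Scan many proteins with the PSSM set
#'
#' @param proteins Named character vector of sequences.
#' @inheritParams scan_motifs
#' @return Row-bound domain-hit data.frame over all proteins.
#' @export
scan_proteins <- function(proteins, pssms = default_pssms()) {
  stopifnot(!is.null(names(proteins)))
  do.call(rbind, c(list(empty_hits()),
                   lapply(names(proteins), function(id)
                     scan_motifs(proteins[[id]], pssms, id = id))))
}

#' Parse an hmmscan per-domain table
#'
#' Reads the whitespace-delimited per-domain tabular output of
#' `hmmscan --domtblout` (lines starting with `#` are comments). The domain
#' (target) name, query protein, independent E-value, domain bit score and
#' alignment coordinates are retained.
#'
#' @param path Path to the table.
#' @return A domain-hit data.frame as in [scan_motifs()].
#' @export
parse_domain_table <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  hits <- empty_hits()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22)
      stop("malformed domain-table row at line ", i, ": expected >= 22 ",
           "fields, got ", length(f), call. = FALSE)
    ali_start <- suppressWarnings(as.integer(f[18]))
    ali_end <- suppressWarnings(as.integer(f[19]))
    e_value <- suppressWarnings(as.numeric(f[13]))
    bit_score <- suppressWarnings(as.numeric(f[14]))
    if (anyNA(c(ali_start, ali_end, e_value, bit_score)))
      stop("malformed domain-table row at line ", i,
           ": non-numeric score or coordinate", call. = FALSE)
    if (ali_start < 1L || ali_end < ali_start)
      stop("invalid alignment coordinates at line ", i, ": ",
           ali_start, "-", ali_end, call. = FALSE)
    hits <- rbind(hits, data.frame(
      protein_id = f[4], domain_label = f[1],
      ali_start = ali_start, ali_end = ali_end,
      bit_score = bit_score, e_value = e_value,
      stringsAsFactors = FALSE
    ))
  }
  hits
}

#' Select family members by domain co-occurrence
#'
#' A protein is a family member iff it has at least one retained hit for
#' every required domain label. Hits with an E-value above `max_evalue` are
#' discarded first; `NA` E-values (PSSM mode, which thresholds on score)
#' always pass.
#'
#' @param proteins Named character vector of sequences.
#' @param hits Domain-hit data.frame.
#' @param require Character vector of required domain labels
#'   (default `c("NAF", "Pkinase")`, the CIPK signature).
#' @param max_evalue Per-domain E-value cutoff for tabular hits
#'   (default 1e-5).
#' @return Sorted character vector of member protein ids.
#' @export
select_family <- function(proteins, hits, require = c("NAF", "Pkinase"),
                          max_evalue = 1e-5) {
  if (length(require) == 0)
    stop("at least one required domain label is needed", call. = FALSE)
  unknown <- setdiff(hits$protein_id, names(proteins))
  if (length(unknown) > 0)
    stop("hits refer to unknown protein(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  ok <- is.na(hits$e_value) | hits$e_value <= max_evalue
  hits <- hits[ok, , drop = FALSE]
  members <- Filter(function(id) {
    labs <- hits$domain_label[hits$protein_id == id]
    all(require %in% labs)
  }, names(proteins))
  sort(unlist(members, use.names = FALSE))
}
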