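# Gene models, exon/intron structure and catalog validation.
#
# Coordinates are 1-based inclusive throughout (GFF3 convention). The
# intron-clade thresholds follow the CIPK literature: fewer than 3 introns
# is intron-poor, more than 8 is intron-rich; the gap in between gets an
# explicit "intermediate" label so the classification partitions all counts.

#' Parse gene models from a GFF3 file
#'
#' Reads `gene`/`mRNA`/`exon`/`CDS` features. When a gene has several mRNAs
#' the transcript with the longest total CDS is selected, the usual
#' representative-transcript rule for gene-structure summaries.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of gene models, each a list with `gene_id`,
#'   `chromosome`, `strand`, `exons` (data.frame of sorted 1-based inclusive
#'   `start`, `end`) and `cds_length_bp`.
#' @export
parse_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gff <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    stringsAsFactors = FALSE
  )
  gff$parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p) == 0) NA_character_ else p[[1]], character(1))

  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  cdss <- gff[gff$type == "CDS", , drop = FALSE]

  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tx <- mrnas[mrnas$parent %in% g$id, , drop = FALSE]
    if (nrow(tx) == 0)
      stop("gene ", g$id, " has no mRNA feature", call. = FALSE)
    cds_len <- vapply(tx$id, function(t) {
      seg <- cdss[cdss$parent %in% t, , drop = FALSE]
      sum(seg$end - seg$start + 1L)
    }, numeric(1))
    best <- tx$id[which.max(cds_len)]
    ex <- exons[exons$parent %in% best, , drop = FALSE]
    ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
    if (any(ex$start < g$start | ex$end > g$end))
      stop("exon outside gene span for ", g$id, call. = FALSE)
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in ", g$id, call. = FALSE)
    list(gene_id = g$id, chromosome = g$seqid, strand = g$strand,
         exons = data.frame(start = ex$start, end = ex$end),
         cds_length_bp = unname(max(cds_len)))
  })
  names(models) <- genes$id
  models
}

#' Number of introns of a gene model
#'
#' @param model A gene model from [parse_gff3()].
#' @return `nrow(exons) - 1`.
#' @export
count_introns <- function(model) {
  nrow(model$exons) - 1L
}

#' Classify a gene by intron count into structural clades
#'
#' Fewer than 3 introns is `intron_poor`, more than 8 is `intron_rich`;
#' counts of 3-8 are `intermediate` (no soybean CIPK gene falls there, but
#' arbitrary inputs may).
#'
#' @param n_introns Non-negative integer vector of intron counts.
#' @return Character vector of clade labels.
#' @export
classify_intron_clade <- function(n_introns) {
  stopifnot(all(n_introns >= 0))
  ifelse(n_introns < 3, "intron_poor",
         ifelse(n_introns > 8, "intron_rich", "intermediate"))
}

#' Gene length from chromosomal coordinates
#'
#' Length of a 1-based inclusive span. Reversed coordinates (start > end,
#' as printed for some catalog rows) are normalized with a warning.
#'
#' @param start,end Positive integer vectors.
#' @return `abs(end - start) + 1`.
#' @export
gene_length <- function(start, end) {
  stopifnot(all(start > 0), all(end > 0))
  if (any(start > end))
    warning("reversed coordinates normalized for ", sum(start > end),
            " span(s)", call. = FALSE)
  abs(end - start) + 1
}

#' Protein length implied by a CDS length
#'
#' `cds/3 - 1`: the stop codon is excluded from the amino-acid count.
#'
#' @param cds_length_bp CDS length(s) in bp, divisible by 3.
#' @return Amino-acid count(s).
#' @export
aa_from_cds <- function(cds_length_bp) {
  stopifnot(all(cds_length_bp > 0))
  if (any(cds_length_bp %% 3 != 0))
    stop("CDS length not divisible by 3", call. = FALSE)
  cds_length_bp / 3 - 1
}

#' Read a gene catalog table
#'
#' The catalog is a TSV mirroring the classic family table: `name`,
#' `gene_id`, `chromosome`, `start`, `end`, `gene_length_bp`, `aa_length`,
#' `pi`, `mw_kd`, `exon_count`, `cds_length_bp`.
#'
#' @param path Path to the TSV.
#' @return A data.frame of gene records.
#' @export
read_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "gene_id", "chromosome", "start", "end",
              "gene_length_bp", "aa_length", "pi", "mw_kd", "exon_count",
              "cds_length_bp")
  missing <- setdiff(needed, names(cat))
  if (length(missing) > 0)
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cat
}

#' Write a gene catalog table
#' @param catalog Catalog data.frame.
#' @param path Output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged soybean CIPK gene catalog
#'
#' The 52-gene soybean CIPK catalog (names, Phytozome gene ids, Wm82.a2.v1
#' coordinates, printed gene/CDS/protein lengths, pI, MW and exon counts)
#' shipped as a plain-text fixture. Two rows are internally inconsistent as
#' printed (a zero-width span and a reversed span); [validate_catalog()]
#' flags them.
#'
#' @return The catalog data.frame (52 rows).
#' @export
soybean_cipk_catalog <- function() {
  read_catalog(system.file("extdata", "gmcipk_catalog.tsv",
                           package = "cipkfam", mustWork = TRUE))
}

#' Validate internal consistency of a gene catalog
#'
#' Quality control over printed family tables: flags rows where the printed
#' gene length disagrees with the coordinate span, the printed amino-acid
#' length disagrees with `cds/3 - 1`, or the coordinates are reversed.
#'
#' @param catalog Catalog data.frame ([read_catalog()]).
#' @return A data.frame of flags: `name`, `check`, `expected`, `found`;
#'   zero rows when the catalog is self-consistent.
#' @export
validate_catalog <- function(catalog) {
  flags <- data.frame(name = character(), check = character(),
                      expected = numeric(), found = numeric(),
                      stringsAsFactors = FALSE)
  add <- function(flags, name, check, expected, found)
    rbind(flags, data.frame(name = name, check = check, expected = expected,
                            found = found, stringsAsFactors = FALSE))
  for (i in seq_len(nrow(catalog))) {
    r <- catalog[i, ]
    if (r$start > r$end)
      flags <- add(flags, r$name, "reversed_coordinates", r$end, r$start)
    span <- abs(r$end - r$start) + 1
    if (span != r$gene_length_bp)
      flags <- add(flags, r$name, "coordinate_span", span, r$gene_length_bp)
    aa <- r$cds_length_bp / 3 - 1
    if (r$cds_length_bp %% 3 != 0 || aa != r$aa_length)
      flags <- add(flags, r$name, "aa_vs_cds", aa, r$aa_length)
  }
  flags
}
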