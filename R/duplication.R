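# Chromosomal distribution, tandem arrays and segmental-duplication pairs.
#
# Tandem rule: two or more family genes on the same chromosome count as a
# tandem array when consecutive members are separated by less than 100 kb
# (measured end-of-upstream to start-of-downstream) and, when a full gene
# annotation is available, by at most five intervening non-family genes.
# Without an annotation the intervening-gene condition is vacuously
# satisfied (distance-only mode). Segmental assignments are read off an
# externally supplied table of duplicated chromosome blocks: a gene lies in
# a block when its span is contained in either side.

normalize_coords <- function(catalog) {
  rev <- catalog$start > catalog$end
  if (any(rev)) {
    tmp <- catalog$start[rev]
    catalog$start[rev] <- catalog$end[rev]
    catalog$end[rev] <- tmp
  }
  catalog
}

#' Per-chromosome gene counts
#'
#' @param genes Catalog data.frame with a `chromosome` column.
#' @return Named integer vector of counts (chromosomes with zero genes are
#'   absent); sums to `nrow(genes)`.
#' @export
chromosome_counts <- function(genes) {
  if (nrow(genes) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(genes$chromosome)
  stats::setNames(as.integer(tab), names(tab))
}

#' Detect tandem duplication arrays
#'
#' Consecutive family genes on a chromosome are linked when the gap from the
#' end of the upstream gene to the start of the downstream gene is below
#' `max_gap` and (if `annotation` is supplied) at most `max_intervening`
#' non-family genes lie strictly between them; linked runs merge into
#' maximal arrays.
#'
#' @param genes Catalog data.frame (`name`, `chromosome`, `start`, `end`).
#'   Reversed coordinates are normalized first.
#' @param annotation Optional full gene annotation (`chromosome`, `start`,
#'   `end`, and an id column `name` or `gene_id`) used for the
#'   intervening-gene condition; `NULL` (default) enables distance-only
#'   mode.
#' @param max_gap Maximum intergenic gap in bp (default 1e5: the 100-kb
#'   rule).
#' @param max_intervening Maximum number of intervening non-family genes
#'   (default 5).
#' @return A list of tandem arrays, each a list with `chromosome`,
#'   `members` (gene names ordered by position) and `gaps_bp`.
#' @export
find_tandem <- function(genes, annotation = NULL, max_gap = 1e5,
                        max_intervening = 5) {
  genes <- normalize_coords(genes)
  if (!is.null(annotation)) {
    annotation <- normalize_coords(annotation)
    ann_id <- if ("name" %in% names(annotation)) annotation$name
              else annotation$gene_id
    fam_id <- genes$name
  }
  arrays <- list()
  for (chrom in sort(unique(genes$chromosome))) {
    g <- genes[genes$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    if (nrow(g) < 2) next
    current <- g$name[1]; gaps <- numeric(0)
    flush <- function() {
      if (length(current) >= 2)
        arrays[[length(arrays) + 1]] <<- list(chromosome = chrom,
                                              members = current,
                                              gaps_bp = gaps)
    }
    for (i in 2:nrow(g)) {
      gap <- g$start[i] - g$end[i - 1]
      linked <- gap < max_gap
      if (linked && !is.null(annotation)) {
        between <- annotation$chromosome == chrom &
          annotation$start > g$end[i - 1] &
          annotation$end < g$start[i] &
          !(ann_id %in% fam_id)
        linked <- sum(between) <= max_intervening
      }
      if (linked) {
        current <- c(current, g$name[i]); gaps <- c(gaps, gap)
      } else {
        flush(); current <- g$name[i]; gaps <- numeric(0)
      }
    }
    flush()
  }
  arrays
}

#' Read a segmental-duplication block table
#'
#' TSV with columns `block_id`, `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#' `start_b`, `end_b` (1-based inclusive).
#'
#' @param path Path to the TSV.
#' @return Block data.frame.
#' @export
read_blocks <- function(path) {
  blocks <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("block_id", "chrom_a", "start_a", "end_a", "chrom_b",
              "start_b", "end_b")
  missing <- setdiff(needed, names(blocks))
  if (length(missing) > 0)
    stop("block table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(blocks$start_a > blocks$end_a | blocks$start_b > blocks$end_b))
    stop("block with start > end", call. = FALSE)
  blocks
}

#' Assign genes to segmental-duplication blocks
#'
#' A gene is block-assigned when its span lies entirely within either side
#' of a block. Genes assigned to the two sides of the same block are
#' reported as duplicate partners; a gene inside a block with no family
#' partner on the mate side still counts as "in a duplicated block".
#'
#' @param genes Catalog data.frame (`name`, `chromosome`, `start`, `end`).
#' @param blocks Block data.frame ([read_blocks()]).
#' @return A list: `assignments` (data.frame gene/block/side), `pairs`
#'   (data.frame gene_a/gene_b/block), `singletons` (gene names outside all
#'   blocks), and `counts` (`n_in_blocks`, `n_blocks_hit`, `n_outside`).
#' @export
assign_segmental <- function(genes, blocks) {
  genes <- normalize_coords(genes)
  assignments <- data.frame(name = character(), block_id = character(),
                            side = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (j in seq_len(nrow(blocks))) {
      b <- blocks[j, ]
      if (g$chromosome == b$chrom_a && g$start >= b$start_a &&
          g$end <= b$end_a)
        assignments <- rbind(assignments, data.frame(
          name = g$name, block_id = as.character(b$block_id), side = "a",
          stringsAsFactors = FALSE))
      if (g$chromosome == b$chrom_b && g$start >= b$start_b &&
          g$end <= b$end_b)
        assignments <- rbind(assignments, data.frame(
          name = g$name, block_id = as.character(b$block_id), side = "b",
          stringsAsFactors = FALSE))
    }
  }
  pairs <- data.frame(gene_a = character(), gene_b = character(),
                      block_id = character(), stringsAsFactors = FALSE)
  for (bid in unique(assignments$block_id)) {
    a_side <- assignments$name[assignments$block_id == bid &
                                 assignments$side == "a"]
    b_side <- assignments$name[assignments$block_id == bid &
                                 assignments$side == "b"]
    if (length(a_side) > 0 && length(b_side) > 0)
      pairs <- rbind(pairs, expand.grid(gene_a = a_side, gene_b = b_side,
                                        block_id = bid,
                                        stringsAsFactors = FALSE))
  }
  in_blocks <- unique(assignments$name)
  singletons <- setdiff(genes$name, in_blocks)
  list(
    assignments = assignments,
    pairs = pairs,
    singletons = singletons,
    counts = c(n_in_blocks = length(in_blocks),
               n_blocks_hit = length(unique(assignments$block_id)),
               n_outside = length(singletons))
  )
}

#' Export gene positions as BED
#'
#' BED is 0-based half-open; 1-based inclusive catalog coordinates are
#' shifted accordingly.
#'
#' @param genes Catalog data.frame.
#' @param path Output BED path.
#' @export
write_gene_bed <- function(genes, path) {
  genes <- normalize_coords(genes)
  bed <- data.frame(chrom = genes$chromosome, start = genes$start - 1L,
                    end = genes$end, name = genes$name)
  utils::write.table(bed[order(bed$chrom, bed$start), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
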