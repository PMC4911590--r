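# Synthetic genome / domain / expression fixtures with planted ground truth.
#
# The generator emulates the study design of a genome-wide CIPK survey:
# family members carrying both planted domains plus single-domain decoys,
# tandem clusters with sub-100-kb gaps, paired segmental blocks, planted
# per-gene intron counts, two-stage microarray log-ratios with planted
# up/down patterns, and qRT-PCR Ct tables with planted fold changes and
# Gaussian cycle noise. Every stage downstream can therefore be checked
# against a truth record without any genome download.

# Per-gene intron counts of the 52-gene soybean CIPK catalog (exons - 1, in
# catalog order): the default planted intron-count distribution.
SOYBEAN_INTRON_COUNTS <- c(
  0, 0, 13, 0, 0, 12, 2, 11, 1, 13, 0, 0, 13, 0, 13, 0, 0, 9, 11, 14,
  0, 0, 0, 0, 0, 0, 0, 1, 11, 13, 0, 0, 1, 14, 0, 0, 1, 0, 11, 0,
  13, 11, 14, 0, 13, 0, 1, 0, 0, 0, 2, 0
)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic family generator
#'
#' Defaults mirror the soybean CIPK study design: 52 members with the
#' catalog's intron-count distribution across 20 chromosomes, six tandem
#' clusters of two genes (gaps well under 100 kb), and segmental pairs on
#' distinct chromosomes.
#'
#' @param n_members Number of family members (>= 2).
#' @param n_decoys_kinase_only,n_decoys_naf_only Decoy proteins carrying
#'   only one of the two planted domains.
#' @param n_chromosomes Number of chromosomes.
#' @param tandem_clusters Data.frame with columns `chromosome` (index),
#'   `size`, `max_gap_bp`; each cluster's intergenic gaps are drawn below
#'   `max_gap_bp` (must be < 1e5 for the cluster to be tandem by
#'   construction).
#' @param segmental_pairs Number of planted segmental-duplication pairs
#'   (each pair on two different chromosomes).
#' @param intron_counts Integer vector of per-member intron counts (length
#'   `n_members`).
#' @param motif_mutation_rate Per-position mutation probability inside the
#'   planted domain motifs.
#' @param n_seed_groups Number of ancestral seed sequences; members are
#'   mutated copies of their group's seed, so groups are recoverable by
#'   phylogeny. Intron-poor members all descend from the last group,
#'   mirroring the intron-poor subgroup of the real family.
#' @param protein_length Length (aa) of every generated protein.
#' @param seed RNG seed; fixed seed gives byte-identical fixtures.
#' @return A `family_config` list, validated.
#' @export
family_config <- function(n_members = 52,
                          n_decoys_kinase_only = 10,
                          n_decoys_naf_only = 10,
                          n_chromosomes = 20,
                          tandem_clusters = data.frame(
                            chromosome = c(2, 9, 13, 15, 18, 18),
                            size = 2,
                            max_gap_bp = 70000),
                          segmental_pairs = 11,
                          intron_counts = SOYBEAN_INTRON_COUNTS[
                            (seq_len(n_members) - 1) %% 52 + 1],
                          motif_mutation_rate = 0.05,
                          n_seed_groups = 4,
                          protein_length = 420,
                          seed = 1) {
  cfg <- list(n_members = n_members,
              n_decoys_kinase_only = n_decoys_kinase_only,
              n_decoys_naf_only = n_decoys_naf_only,
              n_chromosomes = n_chromosomes,
              tandem_clusters = tandem_clusters,
              segmental_pairs = segmental_pairs,
              intron_counts = as.integer(intron_counts),
              motif_mutation_rate = motif_mutation_rate,
              n_seed_groups = n_seed_groups,
              protein_length = protein_length,
              seed = seed)
  if (n_members < 2) stop("n_members must be >= 2", call. = FALSE)
  if (length(cfg$intron_counts) != n_members)
    stop("intron_counts must have length n_members", call. = FALSE)
  if (any(cfg$intron_counts < 0)) stop("negative intron count",
                                       call. = FALSE)
  if (motif_mutation_rate < 0 || motif_mutation_rate > 1)
    stop("motif_mutation_rate must be a probability", call. = FALSE)
  if (nrow(tandem_clusters) > 0) {
    if (any(tandem_clusters$chromosome > n_chromosomes))
      stop("tandem cluster on nonexistent chromosome", call. = FALSE)
    if (any(tandem_clusters$size < 2))
      stop("tandem cluster size must be >= 2", call. = FALSE)
    if (any(tandem_clusters$max_gap_bp >= 1e5))
      stop("tandem cluster max gap must be < 100 kb by construction",
           call. = FALSE)
    if (sum(tandem_clusters$size) > n_members)
      stop("tandem clusters need more members than available",
           call. = FALSE)
  }
  if (protein_length < 120)
    stop("protein_length too short to host both motifs", call. = FALSE)
  class(cfg) <- "family_config"
  cfg
}

random_protein <- function(n) {
  paste(sample(names(AA_RESIDUE_MASS), n, replace = TRUE), collapse = "")
}

mutate_string <- function(s, rate, positions = NULL) {
  letters <- strsplit(s, "")[[1]]
  idx <- if (is.null(positions)) seq_along(letters) else positions
  hit <- idx[stats::runif(length(idx)) < rate]
  if (length(hit) > 0) {
    repl <- sample(names(AA_RESIDUE_MASS), length(hit), replace = TRUE)
    letters[hit] <- repl
  }
  paste(letters, collapse = "")
}

# Evolve m sequences from one ancestor by recursive bifurcation, mutating
# non-motif positions at `rate` per branch. The hierarchical signal makes
# each group a resolvable clade rather than an unresolved star.
evolve_group <- function(ancestor, m, free_pos, rate) {
  if (m == 1) return(mutate_string(ancestor, rate, free_pos))
  m_left <- ceiling(m / 2)
  left <- mutate_string(ancestor, rate, free_pos)
  right <- mutate_string(ancestor, rate, free_pos)
  c(evolve_group(left, m_left, free_pos, rate),
    evolve_group(right, m - m_left, free_pos, rate))
}

plant_motifs <- function(sequence, kinase_at, naf_at, which = c("both")) {
  letters <- strsplit(sequence, "")[[1]]
  put <- function(letters, motif, at) {
    letters[at:(at + nchar(motif) - 1)] <- strsplit(motif, "")[[1]]
    letters
  }
  if (which %in% c("both", "kinase"))
    letters <- put(letters, KINASE_CONSENSUS, kinase_at)
  if (which %in% c("both", "naf"))
    letters <- put(letters, NAF_CONSENSUS, naf_at)
  paste(letters, collapse = "")
}

write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(features, con)
  invisible(path)
}

gene_gff_lines <- function(name, chrom, start, introns, cds_len,
                           intron_len = 200L) {
  n_exon <- introns + 1L
  exon_len <- rep(cds_len %/% n_exon, n_exon)
  exon_len[1] <- exon_len[1] + cds_len %% n_exon
  starts <- integer(n_exon); ends <- integer(n_exon)
  pos <- start
  for (k in seq_len(n_exon)) {
    starts[k] <- pos
    ends[k] <- pos + exon_len[k] - 1L
    pos <- ends[k] + 1L + intron_len
  }
  gend <- ends[n_exon]
  lines <- c(
    sprintf("%s\tcipkfam\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
            chrom, start, gend, name, name),
    sprintf("%s\tcipkfam\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
            chrom, start, gend, name, name)
  )
  phase <- 0L
  for (k in seq_len(n_exon)) {
    lines <- c(lines,
      sprintf("%s\tcipkfam\texon\t%d\t%d\t.\t+\t.\tID=%s.t1.exon%d;Parent=%s.t1",
              chrom, starts[k], ends[k], name, k, name),
      sprintf("%s\tcipkfam\tCDS\t%d\t%d\t.\t+\t%d\tID=%s.t1.cds;Parent=%s.t1",
              chrom, starts[k], ends[k], phase, name, name))
    phase <- (3L - (sum(exon_len[seq_len(k)]) %% 3L)) %% 3L
  }
  list(lines = lines, start = start, end = gend, span = gend - start + 1L)
}

#' Generate a synthetic gene family with planted ground truth
#'
#' Emits a protein FASTA, a GFF3 of gene models, a Table-1-style catalog of
#' the family members, a segmental-block table and a YAML truth record.
#' Every member protein carries a (possibly mutated) copy of the kinase
#' consensus motif followed by the NAF consensus motif; kinase-only and
#' NAF-only decoys lack exactly one of the two. GFF3 exon counts equal the
#' planted intron counts plus one; declared tandem clusters satisfy the
#' sub-100-kb gap rule; segmental pairs sit inside the paired block sides.
#'
#' All proteins share one length, so the member FASTA is column-aligned as
#' emitted and can feed the phylogeny stage directly.
#'
#' @param config A [family_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (fasta, gff3, catalog, blocks,
#'   truth), the in-memory `proteins`, `catalog`, `blocks` and the `truth`
#'   record.
#' @export
generate_family <- function(config, dir) {
  stopifnot(inherits(config, "family_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    L <- config$protein_length
    kinase_at <- 30L
    naf_at <- L - nchar(NAF_CONSENSUS) - 29L
    motif_pos <- c(kinase_at:(kinase_at + nchar(KINASE_CONSENSUS) - 1L),
                   naf_at:(naf_at + nchar(NAF_CONSENSUS) - 1L))

    # ancestral seed sequences, one per group, both motifs planted exactly
    seeds <- vapply(seq_len(config$n_seed_groups), function(g)
      plant_motifs(random_protein(L), kinase_at, naf_at, "both"),
      character(1))

    members <- sprintf("SYNCIPK%02d", seq_len(config$n_members))
    clade <- classify_intron_clade(config$intron_counts)
    group <- integer(config$n_members)
    group[clade == "intron_poor"] <- config$n_seed_groups
    rich_idx <- which(clade != "intron_poor")
    if (length(rich_idx) > 0)
      group[rich_idx] <- (seq_along(rich_idx) - 1L) %%
        max(1L, config$n_seed_groups - 1L) + 1L

    proteins <- character(0)
    free_pos <- setdiff(seq_len(L), motif_pos)
    for (g in seq_len(config$n_seed_groups)) {
      idx <- which(group == g)
      if (length(idx) == 0) next
      evolved <- evolve_group(seeds[g], length(idx), free_pos, 0.04)
      for (k in seq_along(idx)) {
        s <- mutate_string(evolved[k], config$motif_mutation_rate,
                           motif_pos)
        proteins[members[idx[k]]] <- s
      }
    }
    proteins <- proteins[members]
    dk <- if (config$n_decoys_kinase_only > 0)
      sprintf("DECKIN%02d", seq_len(config$n_decoys_kinase_only))
      else character(0)
    dn <- if (config$n_decoys_naf_only > 0)
      sprintf("DECNAF%02d", seq_len(config$n_decoys_naf_only))
      else character(0)
    for (id in dk)
      proteins[id] <- plant_motifs(random_protein(L), kinase_at, naf_at,
                                   "kinase")
    for (id in dn)
      proteins[id] <- plant_motifs(random_protein(L), kinase_at, naf_at,
                                   "naf")

    # genome layout: tandem-cluster members first, then spaced placement
    chroms <- sprintf("Chr%02d", seq_len(config$n_chromosomes))
    chrom_len <- 5e7
    cds_len <- 3L * (L + 1L)
    placement <- data.frame(name = character(), chromosome = character(),
                            start = integer(), introns = integer(),
                            stringsAsFactors = FALSE)
    tandem_truth <- list()
    member_introns <- stats::setNames(config$intron_counts, members)
    next_member <- 1L
    cluster_cursor <- stats::setNames(rep(3e7, config$n_chromosomes),
                                      chroms)
    for (ci in seq_len(nrow(config$tandem_clusters))) {
      cl <- config$tandem_clusters[ci, ]
      chrom <- chroms[cl$chromosome]
      ids <- members[next_member:(next_member + cl$size - 1L)]
      next_member <- next_member + cl$size
      pos <- cluster_cursor[chrom]
      arr <- character(0)
      for (id in ids) {
        span <- cds_len + 200L * member_introns[[id]]
        if (pos + span > chrom_len)
          stop("impossible layout: cluster exceeds chromosome span",
               call. = FALSE)
        placement <- rbind(placement, data.frame(
          name = id, chromosome = chrom, start = as.integer(pos),
          introns = member_introns[[id]], stringsAsFactors = FALSE))
        arr <- c(arr, id)
        gap <- floor(stats::runif(1, 200, cl$max_gap_bp - span))
        pos <- pos + span + gap
      }
      cluster_cursor[chrom] <- pos + 5e5
      tandem_truth[[length(tandem_truth) + 1]] <-
        list(chromosome = chrom, members = arr)
    }
    loose <- c(members[seq_len(config$n_members) >= next_member], dk, dn)
    loose_introns <- c(member_introns[members[members %in% loose]],
                       stats::setNames(rep(0L, length(dk) + length(dn)),
                                       c(dk, dn)))
    cursor <- stats::setNames(rep(1e6, config$n_chromosomes), chroms)
    for (k in seq_along(loose)) {
      id <- loose[k]
      chrom <- chroms[(k - 1L) %% config$n_chromosomes + 1L]
      span <- cds_len + 200L * loose_introns[[id]]
      placement <- rbind(placement, data.frame(
        name = id, chromosome = chrom, start = as.integer(cursor[chrom]),
        introns = loose_introns[[id]], stringsAsFactors = FALSE))
      cursor[chrom] <- cursor[chrom] + span + 5e5
    }

    # gene models
    gff_lines <- character(0)
    ends <- stats::setNames(integer(nrow(placement)), placement$name)
    for (i in seq_len(nrow(placement))) {
      p <- placement[i, ]
      g <- gene_gff_lines(p$name, p$chromosome, p$start, p$introns,
                          cds_len)
      gff_lines <- c(gff_lines, g$lines)
      ends[p$name] <- g$end
    }

    # segmental blocks: pair loose (non-tandem) members across chromosomes
    pool <- placement[placement$name %in%
                        setdiff(members,
                                unlist(lapply(tandem_truth, `[[`,
                                              "members"))), ,
                      drop = FALSE]
    blocks <- data.frame(block_id = character(), chrom_a = character(),
                         start_a = integer(), end_a = integer(),
                         chrom_b = character(), start_b = integer(),
                         end_b = integer(), stringsAsFactors = FALSE)
    seg_truth <- list()
    bi <- 0L; used <- character(0)
    for (i in seq_len(nrow(pool))) {
      if (bi >= config$segmental_pairs) break
      a <- pool[i, ]
      if (a$name %in% used) next
      mate <- pool[pool$chromosome != a$chromosome &
                     !(pool$name %in% c(used, a$name)), , drop = FALSE]
      if (nrow(mate) == 0) next
      b <- mate[1, ]
      bi <- bi + 1L
      used <- c(used, a$name, b$name)
      blocks <- rbind(blocks, data.frame(
        block_id = sprintf("BLK%02d", bi),
        chrom_a = a$chromosome, start_a = max(1L, a$start - 25000L),
        end_a = ends[a$name] + 25000L,
        chrom_b = b$chromosome, start_b = max(1L, b$start - 25000L),
        end_b = ends[b$name] + 25000L, stringsAsFactors = FALSE))
      seg_truth[[bi]] <- list(block_id = sprintf("BLK%02d", bi),
                              gene_a = a$name, gene_b = b$name)
    }
    if (bi < config$segmental_pairs)
      stop("impossible layout: not enough unpaired members on distinct ",
           "chromosomes for the requested segmental pairs", call. = FALSE)

    # member catalog (Table-1-like)
    mem_place <- placement[match(members, placement$name), , drop = FALSE]
    catalog <- data.frame(
      name = members,
      gene_id = tolower(members),
      chromosome = mem_place$chromosome,
      start = mem_place$start,
      end = unname(ends[members]),
      gene_length_bp = unname(ends[members]) - mem_place$start + 1L,
      aa_length = L,
      pi = round(vapply(proteins[members], compute_pi, numeric(1)), 2),
      mw_kd = round(vapply(proteins[members], compute_mw, numeric(1)), 2),
      exon_count = config$intron_counts + 1L,
      cds_length_bp = cds_len,
      stringsAsFactors = FALSE
    )

    truth <- list(
      members = members,
      decoys_kinase_only = dk,
      decoys_naf_only = dn,
      group = as.list(stats::setNames(group, members)),
      intron_counts = as.list(member_introns),
      clade = as.list(stats::setNames(clade, members)),
      tandem_arrays = tandem_truth,
      segmental_pairs = seg_truth,
      protein_length = L,
      cds_length_bp = cds_len,
      seed = config$seed
    )

    paths <- list(
      fasta = file.path(dir, "proteins.faa"),
      gff3 = file.path(dir, "genes.gff3"),
      catalog = file.path(dir, "catalog.tsv"),
      blocks = file.path(dir, "blocks.tsv"),
      truth = file.path(dir, "truth.yml")
    )
    Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins),
                                paths$fasta)
    write_gff3(gff_lines, paths$gff3)
    write_catalog(catalog, paths$catalog)
    utils::write.table(blocks, paths$blocks, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(truth, paths$truth)

    invisible(list(paths = paths, proteins = proteins, catalog = catalog,
                   blocks = blocks, truth = truth))
  })
}

#' Configuration for the synthetic expression generator
#'
#' @param planted_log2fc Optional long data.frame (`gene`, `tissue`,
#'   `timepoint`, `log2fc`) of planted drought log2 fold changes; when
#'   `NULL` a per-gene linear ramp to a random peak is planted (zero at day
#'   0). The reference gene must have zero planted effect.
#' @param ct_noise_sd Gaussian noise SD (cycles) added independently to
#'   every Ct measurement (default 0.3, a typical replicate SD).
#' @param reference_gene Reference (housekeeping) gene id.
#' @param n_bio_reps Biological replicates per condition (>= 2; default 3,
#'   the classic design of three biological replicates).
#' @param tissues,timepoints Sampled tissues and drought timepoints (days);
#'   defaults: leaf/stem/root at 0, 4, 8, 12 days.
#' @param stage_pattern Planted two-stage microarray pattern: counts of
#'   genes consistently up, consistently down, up-then-down and
#'   down-then-up across the vegetative and reproductive stages (defaults
#'   18/13/2/15 over 48 genes, the published overlap structure).
#' @param n_stage_genes Number of genes with microarray probes (default
#'   48).
#' @param seed RNG seed.
#' @return An `expression_config` list, validated.
#' @export
expression_config <- function(planted_log2fc = NULL,
                              ct_noise_sd = 0.3,
                              reference_gene = "RefS20e",
                              n_bio_reps = 3,
                              tissues = c("leaf", "stem", "root"),
                              timepoints = c(0, 4, 8, 12),
                              stage_pattern = c(both_up = 18,
                                                both_down = 13,
                                                up_down = 2,
                                                down_up = 15),
                              n_stage_genes = 48,
                              seed = 1) {
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  if (n_bio_reps < 2) stop("n_bio_reps must be >= 2", call. = FALSE)
  if (!is.null(planted_log2fc)) {
    stopifnot(all(c("gene", "tissue", "timepoint", "log2fc") %in%
                    names(planted_log2fc)))
    if (any(!is.finite(planted_log2fc$log2fc)))
      stop("planted fold changes must be finite", call. = FALSE)
    ref <- planted_log2fc[planted_log2fc$gene == reference_gene, ,
                          drop = FALSE]
    if (nrow(ref) > 0 && any(ref$log2fc != 0))
      stop("reference gene must have zero planted effect", call. = FALSE)
  }
  if (sum(stage_pattern) > n_stage_genes)
    stop("stage pattern exceeds number of probed genes", call. = FALSE)
  structure(list(planted_log2fc = planted_log2fc,
                 ct_noise_sd = ct_noise_sd,
                 reference_gene = reference_gene,
                 n_bio_reps = n_bio_reps,
                 tissues = tissues, timepoints = timepoints,
                 stage_pattern = stage_pattern,
                 n_stage_genes = n_stage_genes,
                 seed = seed),
            class = "expression_config")
}

#' Generate synthetic expression data with planted ground truth
#'
#' Emits two stage log2-ratio matrices (vegetative and reproductive) with a
#' planted up/down overlap pattern, and a qRT-PCR Ct table in which the
#' expected 2^-ddCt of each (gene, tissue, timepoint) equals the planted
#' fold change. The reference gene has a baseline of 20 cycles and zero
#' planted effect; independent Gaussian noise of SD `ct_noise_sd` is added
#' to every Ct measurement.
#'
#' @param config An [expression_config()].
#' @param genes Character vector of target gene ids.
#' @param dir Optional output directory; when given, TSV/YAML files are
#'   written.
#' @return Invisibly, a list with `ct` (observation data.frame), `stages`
#'   (named list of two log2-ratio vectors), `truth`, and `paths` (when
#'   `dir` is given).
#' @export
generate_expression <- function(config, genes, dir = NULL) {
  stopifnot(inherits(config, "expression_config"), length(genes) >= 1)
  if (config$reference_gene %in% genes)
    stop("reference gene cannot be a target gene", call. = FALSE)
  with_seed(config$seed, {
    planted <- config$planted_log2fc
    if (is.null(planted)) {
      grid <- expand.grid(gene = genes, tissue = config$tissues,
                          timepoint = config$timepoints,
                          stringsAsFactors = FALSE)
      peak <- stats::setNames(
        stats::runif(length(genes) * length(config$tissues), -3, 6),
        paste(rep(genes, times = length(config$tissues)),
              rep(config$tissues, each = length(genes))))
      tmax <- max(config$timepoints)
      grid$log2fc <- peak[paste(grid$gene, grid$tissue)] *
        grid$timepoint / tmax
      planted <- grid
    }
    planted <- planted[planted$gene != config$reference_gene, ,
                       drop = FALSE]

    # Ct table: reference baseline 20 cycles; per-gene target baselines
    # spread over 22-29 cycles; drought Ct shifted down by the planted
    # log2 fold change.
    baseline <- stats::setNames(22 + (seq_along(genes) - 1) %% 8, genes)
    baseline[config$reference_gene] <- 20
    key <- function(g, ti, tp) paste(g, ti, tp, sep = "\r")
    fc <- stats::setNames(planted$log2fc,
                          key(planted$gene, planted$tissue,
                              planted$timepoint))
    rows <- expand.grid(
      bio_replicate = seq_len(config$n_bio_reps),
      gene = c(config$reference_gene, genes),
      condition = c("control", "drought"),
      timepoint = config$timepoints,
      tissue = config$tissues,
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
    )[, c("gene", "tissue", "timepoint", "condition", "bio_replicate")]
    shift <- fc[key(rows$gene, rows$tissue, rows$timepoint)]
    shift[is.na(shift) | rows$condition != "drought"] <- 0
    shift <- unname(shift)
    # Calibrate affected cells so that the *expectation* of the recovered
    # fold (arithmetic mean of per-replicate 2^-ddCt, which is lognormally
    # biased under Gaussian Ct noise) equals the planted fold. ddCt variance
    # per treated replicate is 2*sd^2 (target+reference noise) plus
    # 2*sd^2/n from the averaged control dCt. Unaffected cells (planted
    # fold 1) are left as an exact null for the replicate t-test.
    sigma2_ddct <- 2 * config$ct_noise_sd^2 * (1 + 1 / config$n_bio_reps)
    shift <- ifelse(shift != 0, shift - log(2) / 2 * sigma2_ddct, 0)
    rows$ct <- unname(baseline[rows$gene]) - shift +
      stats::rnorm(nrow(rows), 0, config$ct_noise_sd)
    rownames(rows) <- NULL

    # two-stage microarray log ratios with the planted overlap pattern
    n_probe <- min(config$n_stage_genes, length(genes))
    probed <- genes[seq_len(n_probe)]
    pat <- config$stage_pattern
    signs <- rep(c("uu", "dd", "ud", "du"),
                 times = c(pat[["both_up"]], pat[["both_down"]],
                           pat[["up_down"]], pat[["down_up"]]))
    signs <- c(signs, rep("uu", max(0, n_probe - length(signs))))
    signs <- signs[seq_len(n_probe)]
    mag <- function(n) stats::runif(n, 0.2, 2.5)
    s1 <- ifelse(substr(signs, 1, 1) == "u", 1, -1) * mag(n_probe)
    s2 <- ifelse(substr(signs, 2, 2) == "u", 1, -1) * mag(n_probe)
    stages <- list(vegetative = stats::setNames(s1, probed),
                   reproductive = stats::setNames(s2, probed))

    truth <- list(
      planted_log2fc = planted,
      reference_gene = config$reference_gene,
      reference_baseline_ct = 20,
      target_baseline_ct = as.list(baseline),
      ct_noise_sd = config$ct_noise_sd,
      n_bio_reps = config$n_bio_reps,
      stage_pattern = as.list(config$stage_pattern),
      stage_calls = as.list(stats::setNames(signs, probed)),
      seed = config$seed
    )

    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        ct = file.path(dir, "ct_table.tsv"),
        vegetative = file.path(dir, "stage_vegetative.tsv"),
        reproductive = file.path(dir, "stage_reproductive.tsv"),
        truth = file.path(dir, "truth_expression.yml")
      )
      utils::write.table(rows, paths$ct, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      for (st in c("vegetative", "reproductive"))
        utils::write.table(
          data.frame(gene = names(stages[[st]]),
                     log2_ratio = unname(stages[[st]])),
          paths[[st]], sep = "\t", quote = FALSE, row.names = FALSE)
      truth_out <- truth
      truth_out$planted_log2fc <- NULL   # tabular; kept in-memory only
      yaml::write_yaml(truth_out, paths$truth)
    }
    invisible(list(ct = rows, stages = stages, truth = truth,
                   paths = paths))
  })
}
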