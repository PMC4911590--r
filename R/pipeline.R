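# Orchestration: run every enabled stage from one config and emit a report
# bundle plus a machine-readable summary.

#' Build and validate a pipeline configuration
#'
#' Paths may be omitted for stages that are not enabled. Thresholds default
#' to the package-wide conventions (100-kb tandem gap, 5 intervening genes,
#' E-value 1e-5, sign-rule microarray threshold).
#'
#' @param out_dir Output directory for the report bundle.
#' @param stages Character vector of stages to run, any of `"identify"`,
#'   `"structure"`, `"tree"`, `"duplication"`, `"expression"`.
#' @param fasta Protein FASTA (identify; also the aligned input for `tree`
#'   when `alignment` is not given separately).
#' @param domain_table Optional hmmscan per-domain table; when `NULL` the
#'   built-in PSSM scanner is used.
#' @param alignment Aligned FASTA for the tree stage (defaults to `fasta`).
#' @param catalog Gene catalog TSV (structure, duplication).
#' @param blocks Segmental-block TSV (duplication; optional).
#' @param annotation Optional full-annotation catalog TSV for the
#'   intervening-gene tandem condition.
#' @param stage_vegetative,stage_reproductive Stage log2-ratio TSVs
#'   (expression; optional).
#' @param ct_table qRT-PCR Ct TSV (expression; optional).
#' @param reference_gene Reference gene id for the ddCt stage.
#' @param require_domains Domain labels required for family membership.
#' @param max_evalue,tandem_max_gap,max_intervening,array_threshold
#'   Stage thresholds.
#' @param bootstrap_reps,seed Bootstrap replicate count and RNG seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("identify", "structure",
                                       "duplication"),
                            fasta = NULL, domain_table = NULL,
                            alignment = NULL, catalog = NULL,
                            blocks = NULL, annotation = NULL,
                            stage_vegetative = NULL,
                            stage_reproductive = NULL,
                            ct_table = NULL, reference_gene = NULL,
                            require_domains = c("NAF", "Pkinase"),
                            max_evalue = 1e-5, tandem_max_gap = 1e5,
                            max_intervening = 5, array_threshold = 0,
                            bootstrap_reps = 100, seed = 1) {
  cfg <- as.list(environment())
  known <- c("identify", "structure", "tree", "duplication", "expression")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(tandem_max_gap > 0, max_intervening >= 0, max_evalue > 0,
            bootstrap_reps >= 1, array_threshold >= 0)
  need <- function(stage, field) {
    if (stage %in% stages && is.null(cfg[[field]]))
      stop("stage '", stage, "' needs config field '", field, "'",
           call. = FALSE)
  }
  need("identify", "fasta")
  need("structure", "catalog")
  need("duplication", "catalog")
  if ("tree" %in% stages && is.null(fasta) && is.null(alignment))
    stop("stage 'tree' needs an alignment (or fasta)", call. = FALSE)
  if ("expression" %in% stages && is.null(ct_table) &&
      is.null(stage_vegetative))
    stop("stage 'expression' needs a Ct table or stage matrices",
         call. = FALSE)
  for (f in c("fasta", "domain_table", "alignment", "catalog", "blocks",
              "annotation", "stage_vegetative", "stage_reproductive",
              "ct_table")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config path does not exist: ", f, " = ", cfg[[f]],
           call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML keys are the arguments of [pipeline_config()].
#'
#' @param path YAML config path.
#' @param ... Overrides applied on top of the file values.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

log_line <- function(log, ...) c(log, paste0(...))

#' Run the family-characterization pipeline
#'
#' Executes the enabled stages in order (identify, structure, tree,
#' duplication, expression), writes the report bundle under
#' `config$out_dir`, and returns a machine-readable summary. Any stage
#' failure aborts with the stage name; partial outputs of the failed run
#' are removed. Given a seed the run is deterministic.
#'
#' @param config A [pipeline_config()].
#' @return A list: `summary` (named counts), `outputs` (paths written) and
#'   per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  written <- function(path) { outputs <<- c(outputs, path); path }
  log <- c(paste0("cipkfam pipeline run, seed=", config$seed),
           paste0("stages: ", paste(config$stages, collapse = ", ")),
           paste0("thresholds: tandem_max_gap=", config$tandem_max_gap,
                  " max_intervening=", config$max_intervening,
                  " max_evalue=", config$max_evalue,
                  " array_threshold=", config$array_threshold,
                  " bootstrap_reps=", config$bootstrap_reps))
  summary <- list()
  results <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(outputs)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("identify" %in% config$stages) {
    results$identify <- run_stage("identify", {
      proteins <- read_protein_fasta(config$fasta)
      hits <- if (is.null(config$domain_table))
        scan_proteins(gsub("-", "", proteins)) else
        parse_domain_table(config$domain_table)
      members <- select_family(proteins, hits,
                               require = config$require_domains,
                               max_evalue = config$max_evalue)
      stats <- protein_stats(gsub("-", "", proteins[members]))
      writeLines(members, written(file.path(config$out_dir,
                                            "members.txt")))
      utils::write.table(stats,
                         written(file.path(config$out_dir,
                                           "member_stats.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$n_members <- length(members)
      summary$fraction_pi_above_7 <-
        round(100 * mean(stats$pi > 7), 2)
      list(members = members, stats = stats, hits = hits)
    })
    log <- log_line(log, "identify: ", summary$n_members, " members")
  }

  if ("structure" %in% config$stages) {
    results$structure <- run_stage("structure", {
      cat <- read_catalog(config$catalog)
      introns <- cat$exon_count - 1L
      clade <- classify_intron_clade(introns)
      clade_table <- data.frame(name = cat$name, introns = introns,
                                clade = clade, stringsAsFactors = FALSE)
      utils::write.table(clade_table,
                         written(file.path(config$out_dir,
                                           "clade_table.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      flags <- validate_catalog(cat)
      utils::write.table(flags,
                         written(file.path(config$out_dir,
                                           "validation_report.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$n_genes <- nrow(cat)
      summary$n_intron_poor <- sum(clade == "intron_poor")
      summary$n_intron_rich <- sum(clade == "intron_rich")
      summary$n_intermediate <- sum(clade == "intermediate")
      summary$n_validation_flags <- nrow(flags)
      if (is.null(summary$fraction_pi_above_7))
        summary$fraction_pi_above_7 <- round(100 * mean(cat$pi > 7), 2)
      list(clade_table = clade_table, flags = flags)
    })
    log <- log_line(log, "structure: ", summary$n_intron_poor, " poor / ",
                    summary$n_intron_rich, " rich")
  }

  if ("tree" %in% config$stages) {
    results$tree <- run_stage("tree", {
      aln_path <- if (!is.null(config$alignment)) config$alignment
                  else config$fasta
      aln <- read_alignment(aln_path)
      tree <- bootstrap_support(aln, n_reps = config$bootstrap_reps,
                                seed = config$seed)
      write_tree_newick(tree, written(file.path(config$out_dir,
                                                "tree.nwk")))
      write_distances(alignment_distances(aln),
                      written(file.path(config$out_dir,
                                        "distances.tsv")))
      summary$n_tree_leaves <- length(tree$tip.label)
      tree
    })
    log <- log_line(log, "tree: ", summary$n_tree_leaves, " leaves, ",
                    config$bootstrap_reps, " bootstrap replicates")
  }

  if ("duplication" %in% config$stages) {
    results$duplication <- run_stage("duplication", {
      cat <- suppressWarnings(normalize_coords(read_catalog(
        config$catalog)))
      counts <- chromosome_counts(cat)
      ann <- if (!is.null(config$annotation))
        read_catalog(config$annotation) else NULL
      arrays <- find_tandem(cat, annotation = ann,
                            max_gap = config$tandem_max_gap,
                            max_intervening = config$max_intervening)
      arr_table <- if (length(arrays) == 0)
        data.frame(array = integer(), chromosome = character(),
                   members = character()) else
        data.frame(array = seq_along(arrays),
                   chromosome = vapply(arrays, `[[`, character(1),
                                       "chromosome"),
                   members = vapply(arrays, function(a)
                     paste(a$members, collapse = ","), character(1)))
      utils::write.table(arr_table,
                         written(file.path(config$out_dir,
                                           "tandem_arrays.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_bed(cat, written(file.path(config$out_dir,
                                            "genes.bed")))
      seg <- NULL
      if (!is.null(config$blocks)) {
        seg <- assign_segmental(cat, read_blocks(config$blocks))
        utils::write.table(seg$pairs,
                           written(file.path(config$out_dir,
                                             "segmental_pairs.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$n_genes_in_blocks <- unname(seg$counts["n_in_blocks"])
        summary$n_blocks_hit <- unname(seg$counts["n_blocks_hit"])
        summary$n_genes_outside_blocks <- unname(seg$counts["n_outside"])
      }
      summary$n_chromosomes_occupied <- length(counts)
      summary$max_genes_per_chromosome <- max(counts)
      summary$per_chromosome_counts <- as.list(counts)
      summary$n_tandem_arrays <- length(arrays)
      list(chromosome_counts = counts, arrays = arrays, segmental = seg)
    })
    log <- log_line(log, "duplication: ", summary$n_tandem_arrays,
                    " tandem arrays on ", summary$n_chromosomes_occupied,
                    " chromosomes")
  }

  if ("expression" %in% config$stages) {
    results$expression <- run_stage("expression", {
      out <- list()
      if (!is.null(config$stage_vegetative) &&
          !is.null(config$stage_reproductive)) {
        s1 <- read_stage_matrix(config$stage_vegetative)
        s2 <- read_stage_matrix(config$stage_reproductive)
        calls <- data.frame(
          gene = names(s1),
          vegetative = classify_regulation(s1, config$array_threshold),
          reproductive = classify_regulation(s2, config$array_threshold)[
            names(s1)],
          stringsAsFactors = FALSE)
        utils::write.table(calls,
                           written(file.path(config$out_dir,
                                             "regulation_calls.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        xs <- cross_stage_summary(s1, s2, config$array_threshold)
        summary$n_up_vegetative <- sum(calls$vegetative == "up")
        summary$n_down_vegetative <- sum(calls$vegetative == "down")
        summary$n_up_reproductive <- sum(calls$reproductive == "up")
        summary$n_down_reproductive <- sum(calls$reproductive == "down")
        summary$n_both_up <- unname(xs$counts["both_up"])
        summary$n_both_down <- unname(xs$counts["both_down"])
        summary$n_opposite <- unname(xs$counts["opposite"])
        out$cross_stage <- xs
      }
      if (!is.null(config$ct_table)) {
        if (is.null(config$reference_gene))
          stop("ddCt quantification needs reference_gene", call. = FALSE)
        obs <- read_ct_table(config$ct_table)
        res <- delta_delta_ct(obs, config$reference_gene)
        fold_change_report(res,
                           written(file.path(config$out_dir,
                                             "fold_changes.tsv")))
        summary$n_fold_change_cells <- nrow(res)
        summary$n_significant_cells <- sum(res$significant,
                                            na.rm = TRUE)
        out$fold_changes <- res
      }
      out
    })
    log <- log_line(log, "expression stage done")
  }

  writeLines(log, written(file.path(config$out_dir, "run_log.txt")))
  yaml::write_yaml(summary, written(file.path(config$out_dir,
                                              "summary.yml")))
  list(summary = summary, outputs = outputs, results = results)
}
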