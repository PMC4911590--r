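# Drought-expression analysis: microarray up/down classification across two
# developmental stages, and qRT-PCR relative quantification by 2^-ddCt.
#
# The ddCt convention: per biological replicate, dCt = Ct_target - Ct_ref;
# ddCt = dCt_treated - mean(dCt_control); fold = 2^-ddCt. The reported fold
# is the mean over treated replicates, the SE is sd/sqrt(n), and the t-test
# compares treated vs control dCt values (log2 scale, variance-stabilized)
# with Student's equal-variance test by default.

#' Classify microarray drought responses as up- or down-regulated
#'
#' @param stage Named numeric vector of per-gene log2(drought/control)
#'   ratios for one developmental stage.
#' @param threshold Non-negative magnitude below which a ratio is called
#'   `unchanged` (default 0: pure sign rule, as up/down tallies are usually
#'   reported without a cutoff).
#' @return Named character vector: `up`, `down` or `unchanged` per gene.
#' @export
classify_regulation <- function(stage, threshold = 0) {
  stopifnot(threshold >= 0, all(is.finite(stage)), !is.null(names(stage)))
  out <- ifelse(stage > threshold, "up",
                ifelse(stage < -threshold, "down", "unchanged"))
  stats::setNames(out, names(stage))
}

#' Cross-stage summary of regulation calls
#'
#' Partitions the genes called up or down in both stages into consistently
#' up, consistently down, and opposite-direction sets.
#'
#' @param stage1,stage2 Named log2-ratio vectors (e.g. vegetative and
#'   reproductive stage).
#' @param threshold Passed to [classify_regulation()].
#' @return A list with `counts` (`both_up`, `both_down`, `opposite`),
#'   the corresponding gene-name vectors, and `n_common`.
#' @export
cross_stage_summary <- function(stage1, stage2, threshold = 0) {
  common <- intersect(names(stage1), names(stage2))
  if (length(common) == 0) {
    warning("no genes shared between stages", call. = FALSE)
    return(list(counts = c(both_up = 0L, both_down = 0L, opposite = 0L),
                both_up = character(0), both_down = character(0),
                opposite = character(0), n_common = 0L))
  }
  c1 <- classify_regulation(stage1[common], threshold)
  c2 <- classify_regulation(stage2[common], threshold)
  called <- common[c1 %in% c("up", "down") & c2 %in% c("up", "down")]
  both_up <- called[c1[called] == "up" & c2[called] == "up"]
  both_down <- called[c1[called] == "down" & c2[called] == "down"]
  opposite <- setdiff(called, c(both_up, both_down))
  list(counts = c(both_up = length(both_up), both_down = length(both_down),
                  opposite = length(opposite)),
       both_up = both_up, both_down = both_down, opposite = opposite,
       n_common = length(common))
}

#' Read a qRT-PCR Ct table
#'
#' TSV with columns `gene`, `tissue`, `timepoint`, `condition`,
#' `bio_replicate`, `ct`.
#'
#' @param path Path to the TSV.
#' @return Ct observation data.frame.
#' @export
read_ct_table <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene", "tissue", "timepoint", "condition", "bio_replicate",
              "ct")
  missing <- setdiff(needed, names(obs))
  if (length(missing) > 0)
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(obs$ct <= 0)) stop("non-positive Ct value", call. = FALSE)
  obs
}

#' Relative quantification by the 2^-ddCt method
#'
#' For every (gene, tissue, timepoint) cell, each replicate's dCt is the
#' target Ct minus the reference-gene Ct of the same sample; ddCt per
#' treated replicate is its dCt minus the mean control dCt; the fold change
#' is `2^-ddCt` averaged over treated replicates with SE `sd/sqrt(n)`. The
#' p-value is a two-sample t test on dCt (treated vs control replicates),
#' Student's equal-variance by default.
#'
#' @param obs Ct observation data.frame ([read_ct_table()]).
#' @param ref_gene Reference (housekeeping) gene id, present in every
#'   sample.
#' @param control_condition Condition label of the calibrator samples
#'   (default `"control"`).
#' @param treated_condition Condition label of the stressed samples
#'   (default `"drought"`).
#' @param var_equal Use Student's equal-variance t test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with one row per (gene, tissue, timepoint):
#'   `fold` (2^-ddCt), `se`, `ddct`, `p_value`, `significant`, `n_reps`.
#' @export
delta_delta_ct <- function(obs, ref_gene, control_condition = "control",
                           treated_condition = "drought", var_equal = TRUE,
                           alpha = 0.05) {
  stopifnot(ref_gene %in% obs$gene)
  ref <- obs[obs$gene == ref_gene, , drop = FALSE]
  targets <- setdiff(unique(obs$gene), ref_gene)
  sample_key <- function(d) paste(d$tissue, d$timepoint, d$condition,
                                  d$bio_replicate, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, sample_key(ref))

  out <- NULL
  for (gene in targets) {
    g <- obs[obs$gene == gene, , drop = FALSE]
    key <- sample_key(g)
    if (anyNA(ref_ct[key])) {
      bad <- which(is.na(ref_ct[key]))[1]
      stop("missing reference Ct for sample (", g$tissue[bad], ", day ",
           g$timepoint[bad], ", ", g$condition[bad], ", replicate ",
           g$bio_replicate[bad], ")", call. = FALSE)
    }
    g$dct <- g$ct - unname(ref_ct[key])
    for (tissue in unique(g$tissue)) {
      for (tp in sort(unique(g$timepoint[g$tissue == tissue]))) {
        cell <- g[g$tissue == tissue & g$timepoint == tp, , drop = FALSE]
        trt <- cell$dct[cell$condition == treated_condition]
        ctl <- cell$dct[cell$condition == control_condition]
        if (length(trt) == 0 || length(ctl) == 0) next
        ddct_rep <- trt - mean(ctl)
        fold_rep <- 2^(-ddct_rep)
        n <- length(fold_rep)
        p <- NA_real_
        if (n >= 2 && length(ctl) >= 2 &&
            (stats::sd(trt) > 0 || stats::sd(ctl) > 0)) {
          p <- stats::t.test(trt, ctl, var.equal = var_equal)$p.value
        }
        out <- rbind(out, data.frame(
          gene = gene, tissue = tissue, timepoint = tp,
          fold = mean(fold_rep),
          se = if (n >= 2) stats::sd(fold_rep) / sqrt(n) else 0,
          ddct = mean(ddct_rep),
          p_value = p,
          significant = !is.na(p) & p < alpha,
          n_reps = n,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (is.null(out)) stop("no target-gene cells found", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Long-format fold-change report
#'
#' One row per gene x tissue x timepoint with fold, SE, p-value and a
#' significance star; the day-0 cell of a stress time course is the
#' calibrator, so its fold is 1 by construction when treated and control
#' coincide at day 0.
#'
#' @param results Data.frame from [delta_delta_ct()].
#' @param path Optional output TSV path.
#' @return The report data.frame (invisibly written to `path` if given).
#' @export
fold_change_report <- function(results, path = NULL) {
  report <- results[order(results$gene, results$tissue, results$timepoint),
                    c("gene", "tissue", "timepoint", "fold", "se",
                      "p_value", "significant")]
  report$star <- ifelse(!is.na(report$significant) & report$significant,
                        "*", "")
  rownames(report) <- NULL
  if (!is.null(path))
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  report
}

#' Read a stage log2-ratio matrix
#'
#' TSV with columns `gene` and `log2_ratio`.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of log2 ratios.
#' @export
read_stage_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2_ratio") %in% names(d)))
    stop("stage matrix needs columns gene, log2_ratio", call. = FALSE)
  stats::setNames(d$log2_ratio, d$gene)
}
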