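test_that("regulation calls follow the sign rule and an optional threshold", {
  stage <- c(g1 = 1.2, g2 = -0.4, g3 = 0)
  calls <- classify_regulation(stage)
  expect_equal(unname(calls), c("up", "down", "unchanged"))
  calls2 <- classify_regulation(stage, threshold = 0.5)
  expect_equal(unname(calls2), c("up", "unchanged", "unchanged"))
  expect_error(classify_regulation(c(g = Inf)))
})

test_that("cross-stage summary partitions genes called in both stages", {
  s <- c(a = 1, b = -1, c = 2)
  xs <- cross_stage_summary(s, s)
  expect_equal(unname(xs$counts["opposite"]), 0L)
  expect_equal(sum(xs$counts), 3L)
  expect_warning(empty <- cross_stage_summary(c(a = 1), c(b = 1)),
                 "no genes shared")
  expect_equal(sum(empty$counts), 0L)
})

test_that("planted two-stage pattern reproduces the published overlap structure", {
  genes <- sprintf("g%02d", 1:52)
  ex <- generate_expression(expression_config(seed = 2), genes)
  s1 <- ex$stages$vegetative
  s2 <- ex$stages$reproductive
  expect_length(s1, 48L)
  calls1 <- classify_regulation(s1)
  calls2 <- classify_regulation(s2)
  expect_equal(sum(calls1 == "up"), 20L)
  expect_equal(sum(calls1 == "down"), 28L)
  expect_equal(sum(calls2 == "up"), 33L)
  expect_equal(sum(calls2 == "down"), 15L)
  xs <- cross_stage_summary(s1, s2)
  expect_equal(unname(xs$counts),
               c(18L, 13L, 17L))   # both up, both down, opposite
})

test_that("ddCt arithmetic: a 3-cycle shift is an 8-fold change", {
  obs <- expand.grid(gene = c("tgt", "ref"), condition = c("control",
                                                           "drought"),
                     bio_replicate = 1:3, stringsAsFactors = FALSE)
  obs$tissue <- "leaf"; obs$timepoint <- 4
  obs$ct <- ifelse(obs$gene == "ref", 20,
                   ifelse(obs$condition == "drought", 25, 28))
  res <- delta_delta_ct(obs, "ref")
  expect_equal(res$fold, 8)
  expect_equal(res$ddct, -3)
  expect_equal(res$se, 0)
  expect_true(is.na(res$p_value))   # zero variance, t-test undefined

  # identical treated and control Cts give fold 1, ddCt 0
  obs$ct[obs$gene == "tgt"] <- 26
  res1 <- delta_delta_ct(obs, "ref")
  expect_equal(res1$fold, 1)
  expect_equal(res1$ddct, 0)
})

test_that("missing reference Cts are reported by cell", {
  obs <- data.frame(gene = c("tgt", "tgt"), tissue = "leaf",
                    timepoint = 4, condition = c("control", "drought"),
                    bio_replicate = 1L, ct = c(28, 25))
  obs <- rbind(obs, data.frame(gene = "ref", tissue = "leaf",
                               timepoint = 4, condition = "control",
                               bio_replicate = 1L, ct = 20))
  expect_error(delta_delta_ct(obs, "ref"), "missing reference Ct")
})

test_that("noiseless planted folds are recovered exactly with inverse symmetry", {
  pl <- data.frame(gene = "g1", tissue = "leaf", timepoint = 4,
                   log2fc = 3)
  ex <- generate_expression(expression_config(planted_log2fc = pl,
                                              ct_noise_sd = 0,
                                              tissues = "leaf",
                                              timepoints = c(0, 4)),
                            "g1")
  res <- delta_delta_ct(ex$ct, "RefS20e")
  expect_equal(res$fold[res$timepoint == 4], 8)
  expect_equal(res$se, c(0, 0))
  expect_equal(res$fold[res$timepoint == 0], 1)  # day-0 calibrator
  # swapping the roles of the conditions inverts the fold
  inv <- delta_delta_ct(ex$ct, "RefS20e",
                        control_condition = "drought",
                        treated_condition = "control")
  expect_equal(res$fold * inv$fold, c(1, 1))
})

test_that("planted fold 1 with zero noise yields unit folds and no significance", {
  pl <- expand.grid(gene = c("g1", "g2"), tissue = "leaf",
                    timepoint = c(0, 4), stringsAsFactors = FALSE)
  pl$log2fc <- 0
  ex <- generate_expression(expression_config(planted_log2fc = pl,
                                              ct_noise_sd = 0,
                                              tissues = "leaf",
                                              timepoints = c(0, 4)),
                            c("g1", "g2"))
  res <- delta_delta_ct(ex$ct, "RefS20e")
  expect_true(all(res$fold == 1))
  expect_false(any(res$significant, na.rm = TRUE))
})

test_that("the reference gene against itself is identically 1", {
  obs <- expand.grid(gene = "ref", condition = c("control", "drought"),
                     bio_replicate = 1:3, stringsAsFactors = FALSE)
  obs$tissue <- "leaf"; obs$timepoint <- 4
  obs$ct <- 20 + seq_len(nrow(obs)) / 10
  obs2 <- obs; obs2$gene <- "self"
  res <- delta_delta_ct(rbind(obs, obs2), "ref")
  expect_equal(res$fold, 1)   # dCt of a gene vs itself is 0 everywhere
})

test_that("the fold-change report is complete and day-0 anchored", {
  genes <- c("g1", "g2")
  ex <- generate_expression(expression_config(ct_noise_sd = 0, seed = 3),
                            genes)
  res <- delta_delta_ct(ex$ct, "RefS20e")
  report <- fold_change_report(res)
  expect_equal(nrow(report), length(genes) * 3 * 4)  # tissues x timepoints
  expect_true(all(report$fold[report$timepoint == 0] == 1))
  expect_true(all(c("fold", "se", "p_value", "star") %in% names(report)))
})

test_that("monotone planted fold series stay monotone under zero noise", {
  pl <- data.frame(gene = "g1", tissue = "leaf",
                   timepoint = c(0, 4, 8, 12), log2fc = c(0, 1, 2, 3))
  ex <- generate_expression(expression_config(planted_log2fc = pl,
                                              ct_noise_sd = 0,
                                              tissues = "leaf"),
                            "g1")
  res <- delta_delta_ct(ex$ct, "RefS20e")
  res <- res[order(res$timepoint), ]
  expect_equal(res$fold, c(1, 2, 4, 8))
})

test_that("noisy fold recovery is unbiased over Monte-Carlo seeds", {
  pl <- data.frame(gene = "g1", tissue = "leaf", timepoint = 4,
                   log2fc = 3)
  folds <- vapply(1:60, function(s) {
    ex <- generate_expression(expression_config(planted_log2fc = pl,
                                                ct_noise_sd = 0.3,
                                                tissues = "leaf",
                                                timepoints = 4,
                                                seed = s), "g1")
    delta_delta_ct(ex$ct, "RefS20e")$fold
  }, numeric(1))
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 8), 3 * se)
})
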