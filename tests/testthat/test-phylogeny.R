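test_that("pairwise deletion excludes gapped sites from the p-distance", {
  expect_equal(p_distance_pairwise_deletion("AAAA", "AAAA"), 0)
  expect_equal(p_distance_pairwise_deletion("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance_pairwise_deletion("AA-A", "AAAT"), 1 / 3)
  expect_error(p_distance_pairwise_deletion("--", "AA"), "zero usable")
  expect_error(p_distance_pairwise_deletion("AA", "AAA"), "length")
})

test_that("Poisson correction is monotone with d >= p and fails at saturation", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), 0.693147, tolerance = 1e-6)
  p <- seq(0, 0.95, by = 0.05)
  d <- poisson_correct(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))
  expect_error(poisson_correct(1), "saturated")
})

test_that("three taxa force the unique unrooted topology with three-point lengths", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], (2 + 3 - 4) / 2)
  expect_equal(len[["B"]], (2 + 4 - 3) / 2)
  expect_equal(len[["C"]], (3 + 4 - 2) / 2)
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3 taxa")
})

test_that("the additive 4-taxon example yields split AB|CD with exact lengths", {
  ids <- c("A", "B", "C", "D")
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(dm)
  # the least-squares brute-force oracle over all 3 topologies agrees
  expect_true(same_topology(tr, ls_best_topology(dm)))
  # exact branch lengths: A:1 B:2 C:3 D:4, internal 1
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[ids, ids] - dm)), 0,
               tolerance = 1e-9)
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
})

test_that("permuting taxon order leaves the NJ tree invariant", {
  ra <- random_additive(6, seed = 3)
  tr1 <- nj_tree(ra$dm)
  perm <- sample(6)
  tr2 <- nj_tree(ra$dm[perm, perm])
  expect_true(same_topology(tr1, tr2))
  expect_equal(ape::cophenetic.phylo(tr1)[rownames(ra$dm), rownames(ra$dm)],
               ape::cophenetic.phylo(tr2)[rownames(ra$dm), rownames(ra$dm)],
               tolerance = 1e-9)
})

test_that("NJ recovers random additive trees exactly (consistency)", {
  for (n in c(5, 8, 12)) {
    for (seed in 1:3) {
      ra <- random_additive(n, seed = 100 * n + seed)
      tr <- nj_tree(ra$dm)
      expect_true(same_topology(tr, ra$tree))
      expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(ra$dm),
                                                     rownames(ra$dm)] -
                             ra$dm)), 0, tolerance = 1e-8)
    }
  }
})

test_that("NJ agrees with the least-squares topology oracle on additive matrices up to 7 taxa", {
  for (n in c(5, 6, 7)) {
    ra <- random_additive(n, seed = 17 + n)
    expect_true(same_topology(nj_tree(ra$dm), ls_best_topology(ra$dm)))
  }
})

test_that("negative branch lengths are clamped with the deficit recorded", {
  ids <- c("A", "B", "C")
  dm <- matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3, 3,
               dimnames = list(ids, ids))   # violates triangle inequality
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "negative_branch_deficit"), 0)
})

test_that("bootstrap supports are deterministic, bounded and leaf-order invariant", {
  fam <- small_family(seed = 5, n_members = 8)
  aln <- read_protein_fasta(fam$paths$fasta)[fam$truth$members]
  t1 <- bootstrap_support(aln, n_reps = 60, seed = 4)
  t2 <- bootstrap_support(aln, n_reps = 60, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  t3 <- bootstrap_support(aln[rev(seq_along(aln))], n_reps = 60, seed = 4)
  expect_setequal(t3$node.label, t1$node.label)
})

test_that("an alignment whose every column supports one split gives it 100%", {
  aln <- c(A = "AAAAAAAAAA", B = "AAAAAAAAAA",
           C = "TTTTTTTTTT", D = "TTTTTTTTTT")
  tr <- bootstrap_support(aln, n_reps = 50, seed = 1, model = "p")
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_equal(sup[!is.na(sup)], 100)
})

test_that("bootstrap supports replay exactly from the stored column indices", {
  fam <- small_family(seed = 9, n_members = 6)
  aln <- read_protein_fasta(fam$paths$fasta)[fam$truth$members]
  tr <- bootstrap_support(aln, n_reps = 200, seed = 2,
                          keep_indices = TRUE)
  idx_list <- attr(tr, "replicate_indices")
  expect_length(idx_list, 200)

  # independent recomputation: seqinr-free manual distances + ape::nj
  split_strings <- function(tree) {
    parts <- ape::prop.part(tree)
    tips <- attr(parts, "labels")
    ref <- sort(tips)[1]
    out <- character(0)
    for (p in parts) {
      side <- tips[p]
      if (length(side) == length(tips)) next
      if (ref %in% side) side <- setdiff(tips, side)
      if (length(side) >= 2 && length(side) <= length(tips) - 2)
        out <- c(out, paste(sort(side), collapse = "|"))
    }
    out
  }
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(mat) <- names(aln)
  manual_dist <- function(m) {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      p <- mean(m[i, ok] != m[j, ok])
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
    d
  }
  counts <- integer(0)
  for (idx in idx_list) {
    rep_tree <- ape::nj(stats::as.dist(manual_dist(mat[, idx])))
    for (s in split_strings(rep_tree))
      counts[s] <- if (is.na(counts[s])) 1L else counts[s] + 1L
  }
  ntip <- length(tr$tip.label)
  for (node in seq_len(tr$Nnode) + ntip) {
    s <- cipkfam:::node_split(tr, node)
    lab <- tr$node.label[node - ntip]
    if (is.na(s)) { expect_equal(lab, ""); next }
    hit <- counts[s]
    expect_equal(as.numeric(lab),
                 100 * (if (is.na(hit)) 0 else unname(hit)) / 200)
  }
})

test_that("subgroup labels propagate from anchors and recover planted groups", {
  # caterpillar with one anchor on each side
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,(E:1,F:1):1):1);")
  asg <- assign_subgroups(tr, list(I = "A", II = "F"))
  expect_equal(asg[c("A", "B", "C")], c(A = "I", B = "I", C = "I"))
  expect_equal(asg[c("D", "E", "F")], c(D = "II", E = "II", F = "II"))
  expect_error(assign_subgroups(tr, list(I = "A", II = "A")), "disjoint")

  # planted-partition recovery on a synthetic family from 2 seed groups
  fam <- small_family(seed = 21, n_members = 10)
  aln <- read_protein_fasta(fam$paths$fasta)[fam$truth$members]
  tr2 <- nj_tree(alignment_distances(aln))
  grp <- unlist(fam$truth$group)
  anchors <- lapply(split(names(grp), grp), `[`, 1)
  asg2 <- assign_subgroups(tr2, anchors)
  expect_equal(unname(asg2[names(grp)]), unname(as.character(grp)))
})
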