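# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Brute-force pH grid search for the isoelectric point: evaluates the net
# charge on a fine grid and returns the pH where it crosses zero.
pi_grid_oracle <- function(sequence, step = 1e-5) {
  ph <- seq(0, 14, by = step)
  charge <- net_charge(sequence, ph)
  k <- which(charge <= 0)[1]          # charge is decreasing in pH
  (ph[k - 1] + ph[k]) / 2
}

# Least-squares brute force over all unrooted topologies: fits branch
# lengths to the distance matrix by ordinary least squares on the
# path-edge incidence matrix and returns the topology with minimal SSE.
# The path between tips i and j crosses an edge iff exactly one of the two
# tips lies in the edge's below-tip set.
ls_best_topology <- function(dm) {
  n <- nrow(dm)
  topos <- phangorn::allTrees(n, rooted = FALSE,
                              tip.label = rownames(dm))
  pairs <- t(utils::combn(n, 2))
  y <- dm[pairs]
  best <- NULL; best_sse <- Inf
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]   # `[[` restores compressed tip labels
    n_node <- n + tr$Nnode
    below <- matrix(FALSE, n_node, n)
    below[cbind(seq_len(n), seq_len(n))] <- TRUE
    edge <- tr$edge[order(tr$edge[, 2], decreasing = TRUE), , drop = FALSE]
    # accumulate tip sets bottom-up (children have larger node ids except
    # tips, so process edges by decreasing child id, tips last)
    repeat {
      done <- TRUE
      for (e in seq_len(nrow(edge))) {
        p <- edge[e, 1]; ch <- edge[e, 2]
        if (any(below[ch, ]) && !all(below[p, ] | !below[ch, ])) {
          below[p, ] <- below[p, ] | below[ch, ]
          done <- FALSE
        }
      }
      if (done) break
    }
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (e in seq_len(nrow(tr$edge))) {
      inset <- below[tr$edge[e, 2], ]
      X[, e] <- as.numeric(xor(inset[pairs[, 1]], inset[pairs[, 2]]))
    }
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- tr }
  }
  best
}

# Random additive distance matrix: random unrooted topology with positive
# branch lengths; returns the matrix and the true tree.
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(dm = dm, tree = tr)
}

# Same unrooted topology?
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# One hmmscan-style per-domain table row (>= 22 whitespace fields).
domtbl_row <- function(domain, protein, ievalue, score, astart, aend) {
  paste(domain, "-", 300, protein, "-", 450,
        ievalue, score, 0.1, 1, 1, ievalue, ievalue, score, 0.1,
        1, 280, astart, aend, astart, aend, 0.95, "synthetic hit")
}

# Tiny deterministic synthetic family shared across tests. Families of
# fewer than 10 members skip the duplication layout (too few loose genes).
small_family <- function(seed = 11, n_members = 12) {
  full <- n_members >= 10
  generate_family(
    family_config(
      n_members = n_members,
      n_decoys_kinase_only = 4, n_decoys_naf_only = 4,
      n_chromosomes = 5,
      tandem_clusters = if (full)
        data.frame(chromosome = c(2, 4), size = 2, max_gap_bp = 60000)
      else data.frame(chromosome = integer(), size = integer(),
                      max_gap_bp = integer()),
      segmental_pairs = if (full) 2 else 0,
      intron_counts = rep(c(0, 1, 11, 13), length.out = n_members),
      n_seed_groups = 2,
      seed = seed),
    withr::local_tempdir(.local_envir = parent.frame())
  )
}
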