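# Neighbor-joining phylogeny from aligned protein sequences.
#
# Distances are proportions of differing residues with pairwise deletion of
# gapped sites, optionally Poisson-corrected (d = -ln(1 - p)). The NJ engine
# is the canonical Saitou-Nei agglomeration with a deterministic tie-break
# (lowest index pair after lexicographic ordering of ids), so a given
# distance matrix always yields the same tree. Bootstrap supports are
# mapped onto the bipartitions of the original tree, as MEGA does, not onto
# a consensus tree.

#' Read an aligned protein FASTA file
#'
#' @param path Path to an aligned FASTA file (rows padded with `-`).
#' @return A named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  aln <- read_protein_fasta_gapped(path)
  check_alignment(aln)
  aln
}

read_protein_fasta_gapped <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

check_alignment <- function(aln) {
  if (length(aln) < 2) stop("alignment needs >= 2 sequences", call. = FALSE)
  if (length(unique(nchar(aln))) != 1)
    stop("alignment rows differ in length", call. = FALSE)
  if (anyDuplicated(names(aln)))
    stop("duplicate sequence ids in alignment", call. = FALSE)
  invisible(aln)
}

aln_matrix <- function(aln) {
  check_alignment(aln)
  m <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Pairwise-deletion p-distance between two aligned rows
#'
#' Sites where either row carries a gap (`-` or `.`) are excluded; the
#' distance is the fraction of remaining sites that differ.
#'
#' @param a_row,b_row Equal-length gapped sequences (strings).
#' @return Proportion of differing usable sites.
#' @export
p_distance_pairwise_deletion <- function(a_row, b_row) {
  a <- strsplit(a_row, "")[[1]]
  b <- strsplit(b_row, "")[[1]]
  if (length(a) != length(b))
    stop("aligned rows differ in length", call. = FALSE)
  usable <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  if (!any(usable))
    stop("undefined distance: zero usable (ungapped) sites", call. = FALSE)
  sum(a[usable] != b[usable]) / sum(usable)
}

#' Poisson correction of a p-distance
#'
#' Corrects the observed proportion of differences for multiple hits under
#' a Poisson model of amino-acid substitution: `d = -ln(1 - p)`.
#'
#' @param p Proportion(s) of differing sites in `[0, 1)`.
#' @return Corrected distance(s).
#' @export
poisson_correct <- function(p) {
  stopifnot(all(p >= 0))
  if (any(p >= 1))
    stop("saturated distance: p = 1 cannot be Poisson-corrected",
         call. = FALSE)
  -log(1 - p)
}

#' Distance matrix from a protein alignment
#'
#' @param aln Named character vector of aligned sequences.
#' @param model `"poisson"` (default; Poisson-corrected) or `"p"` (raw
#'   p-distance), both with pairwise deletion of gapped sites.
#' @return A symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
alignment_distances <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- aln_matrix(aln)
  distance_from_matrix(m, model)
}

distance_from_matrix <- function(m, model) {
  n <- nrow(m)
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      usable <- !gap[i, ] & !gap[j, ]
      nu <- sum(usable)
      if (nu == 0)
        stop("undefined distance: zero usable sites for pair ",
             rownames(m)[i], "/", rownames(m)[j], call. = FALSE)
      p <- sum(m[i, usable] != m[j, usable]) / nu
      d[i, j] <- d[j, i] <- if (model == "poisson") poisson_correct(p) else p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: iteratively join the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with
#' branch lengths from the standard two-point formulas. Ties in Q are broken
#' by the lowest index pair after sorting ids lexicographically, so the
#' output is deterministic and invariant to input row order. Negative branch
#' lengths are clamped to zero; the summed deficit is stored in the
#' `"negative_branch_deficit"` attribute.
#'
#' @param dm Symmetric distance matrix with ids as dimnames (n >= 3), or a
#'   `dist` object.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm),
            !is.null(rownames(dm)))
  if (nrow(dm) < 3) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  ord <- order(rownames(dm))
  d <- dm[ord, ord, drop = FALSE]
  labels <- rownames(d)
  nodes <- labels            # newick fragment per active node
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)

  while (length(nodes) > 3) {
    n <- length(nodes)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest (i, j) pair among ties, column-major over upper triangle
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_node <- paste0("(", nodes[i], ":", fmt(li), ",",
                       nodes[j], ":", fmt(lj), ")")
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    rownames(d2) <- colnames(d2) <- as.character(seq_along(nodes))
    d <- d2
  }
  # final three-way join at an unrooted basal trifurcation
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- paste0("(", nodes[1], ":", fmt(la), ",",
                   nodes[2], ":", fmt(lb), ",",
                   nodes[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

# Bipartitions of an unrooted tree as canonical strings. Each non-root
# internal node contributes the split separating its clade from the rest;
# the side not containing the reference (alphabetically first) tip is kept,
# so representations agree across trees with the same tip set.
tree_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  ref <- sort(tips)[1]
  out <- character(0)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) == length(tips)) next   # root: trivial split
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2 || length(side) > length(tips) - 2) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  out
}

# Split string for internal node number `node` (or NA for trivial splits).
node_split <- function(tree, node) {
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  ref <- sort(tips)[1]
  side <- tips[parts[[node - length(tips)]]]
  if (length(side) == length(tips)) return(NA_character_)
  if (ref %in% side) side <- setdiff(tips, side)
  if (length(side) < 2 || length(side) > length(tips) - 2)
    return(NA_character_)
  paste(sort(side), collapse = "|")
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' distance matrix and NJ tree per replicate, and annotates each internal
#' edge of the original tree with the percentage of replicate trees
#' containing the same bipartition. A replicate whose resampled columns
#' leave some pair with no usable sites (or a saturated distance) is
#' redrawn, up to 10 times.
#'
#' @param aln Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (>= 1; 1000 in the classic
#'   protocol).
#' @param seed Integer seed for the column resampling RNG stream.
#' @param model Distance model passed to [alignment_distances()].
#' @param keep_indices Keep the resampled column index list as the
#'   `"replicate_indices"` attribute (for replay/audit).
#' @return The original-tree `phylo` object with `node.label` set to
#'   bootstrap percentages (empty for the basal trifurcation).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              model = c("poisson", "p"),
                              keep_indices = FALSE) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1)
  m <- aln_matrix(aln)
  tree <- nj_tree(distance_from_matrix(m, model))
  L <- ncol(m)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  counts <- integer(0)
  idx_list <- if (keep_indices) vector("list", n_reps) else NULL
  for (rep in seq_len(n_reps)) {
    for (try in seq_len(10L)) {
      idx <- sample.int(L, L, replace = TRUE)
      rep_tree <- tryCatch(nj_tree(distance_from_matrix(m[, idx,
                                                          drop = FALSE],
                                                        model)),
                           error = function(e) NULL)
      if (!is.null(rep_tree)) break
      rep_tree <- NULL
    }
    if (is.null(rep_tree))
      stop("bootstrap replicate undefined after 10 redraws", call. = FALSE)
    if (keep_indices) idx_list[[rep]] <- idx
    for (s in tree_bipartitions(rep_tree)) {
      counts[s] <- if (is.na(counts[s])) 1L else counts[s] + 1L
    }
  }

  ntip <- length(tree$tip.label)
  labs <- vapply(seq_len(tree$Nnode) + ntip, function(node) {
    s <- node_split(tree, node)
    if (is.na(s)) return("")
    hits <- counts[s]
    sprintf("%g", 100 * (if (is.na(hits)) 0L else hits) / n_reps)
  }, character(1))
  tree$node.label <- labs
  if (keep_indices) attr(tree, "replicate_indices") <- idx_list
  tree
}

#' Assign subgroup labels to leaves from anchored exemplars
#'
#' Each unanchored leaf receives the subgroup of the smallest bipartition
#' side containing it and at least one anchor, provided that side contains
#' anchors of exactly one subgroup; if the smallest such side mixes
#' subgroups the leaf is left unassigned (`NA`).
#'
#' @param tree An `ape::phylo` tree.
#' @param anchors Named list: subgroup label -> character vector of anchored
#'   leaf ids. Must be non-empty and disjoint.
#' @return Named character vector: leaf -> subgroup (NA when unassigned).
#' @export
assign_subgroups <- function(tree, anchors) {
  stopifnot(length(anchors) > 0, !is.null(names(anchors)))
  all_anchor <- unlist(anchors, use.names = FALSE)
  if (anyDuplicated(all_anchor))
    stop("anchor sets must be disjoint", call. = FALSE)
  missing <- setdiff(all_anchor, tree$tip.label)
  if (length(missing) > 0)
    stop("anchor(s) not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  anchor_of <- rep(names(anchors), lengths(anchors))
  names(anchor_of) <- all_anchor

  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  sides <- list()
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) == length(tips)) next
    sides <- c(sides, list(side), list(setdiff(tips, side)))
  }
  # pendant-edge sides too: a single leaf and its complement
  for (t in tips) sides <- c(sides, list(t), list(setdiff(tips, t)))
  sides <- unique(sides)
  sizes <- lengths(sides)

  out <- stats::setNames(rep(NA_character_, length(tips)), tips)
  out[all_anchor] <- anchor_of[all_anchor]
  for (leaf in setdiff(tips, all_anchor)) {
    containing <- which(vapply(sides, function(s) leaf %in% s, logical(1)))
    containing <- containing[order(sizes[containing])]
    for (k in containing) {
      groups <- unique(anchor_of[intersect(sides[[k]], all_anchor)])
      if (length(groups) == 0) next
      if (length(groups) == 1) out[leaf] <- groups
      break
    }
  }
  out
}

#' Write a tree to a Newick file
#'
#' Bootstrap supports (if present) are written as internal node labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param dm Symmetric distance matrix.
#' @param path Output path.
#' @export
write_distances <- function(dm, path) {
  utils::write.table(data.frame(id = rownames(dm), dm,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
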