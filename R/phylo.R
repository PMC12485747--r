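#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-criterion agglomeration) with a fully
#' deterministic contract: ties in the Q criterion are broken by the
#' lexicographically lowest pair of taxon indices, and negative branch
#' lengths are clamped to zero (the number clamped is recorded in the
#' \code{"clamped"} attribute). Consistent on additive distance matrices:
#' feeding the tree's path distances back reproduces the input exactly.
#'
#' @param D square symmetric numeric matrix with row/col names; >= 3 taxa
#' @return an unrooted \code{ape::phylo} tree
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nwk <- labels                      # growing newick substrings per cluster
  act <- D
  clamped <- 0L
  cl <- function(x) {
    if (x < 0) {
      clamped <<- clamped + 1L
      0
    } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(act) > 3L) {
    N <- nrow(act)
    r <- rowSums(act)
    Q <- (N - 2) * act - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- cl(0.5 * act[i, j] + (r[i] - r[j]) / (2 * (N - 2)))
    vj <- cl(act[i, j] - (0.5 * act[i, j] + (r[i] - r[j]) / (2 * (N - 2))))
    new_nwk <- paste0("(", nwk[i], ":", fmt(vi), ",", nwk[j], ":", fmt(vj),
                      ")")
    du <- 0.5 * (act[i, ] + act[j, ] - act[i, j])
    keep <- setdiff(seq_len(N), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rownames(act) <- colnames(act) <- NULL
  }
  d <- act
  va <- cl(0.5 * (d[1, 2] + d[1, 3] - d[2, 3]))
  vb <- cl(0.5 * (d[1, 2] + d[2, 3] - d[1, 3]))
  vc <- cl(0.5 * (d[1, 3] + d[2, 3] - d[1, 2]))
  full <- paste0("(", nwk[1], ":", fmt(va), ",", nwk[2], ":", fmt(vb), ",",
                 nwk[3], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = full)
  attr(tree, "clamped") <- clamped
  tree
}

# nontrivial bipartitions of an (effectively unrooted) tree, as canonical
# strings: each split is the sorted tip set on the side NOT containing the
# lexicographically smallest label, so a split and its complement coincide
tree_splits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  ref <- sort(tr$tip.label)[1L]
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  tipsets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- tr$tip.label[i]
  # reverse preorder visits children before parents
  for (nd in rev(unique(tr$edge[, 1]))) {
    tipsets[[nd]] <- unlist(tipsets[as.integer(kids[[as.character(nd)]])])
  }
  internal_children <- tr$edge[, 2][tr$edge[, 2] > ntip]
  splits <- character(0)
  for (nd in internal_children) {
    side <- tipsets[[nd]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(tr$tip.label, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the two trees' nontrivial
#' bipartition sets (unrooted, unnormalized); polytomies are allowed. With
#' \code{normalized = TRUE} the count is divided by 2(n-3), its maximum for
#' binary trees on n leaves.
#'
#' @param t1,t2 \code{ape::phylo} trees over identical leaf sets
#' @param normalized divide by 2(n-3)? (default FALSE)
#' @return nonnegative integer (or fraction when normalized)
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share an identical leaf set")
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) rf / (2 * (length(t1$tip.label) - 3)) else rf
}

#' Pairwise Robinson-Foulds distance matrix over a list of trees
#'
#' @param trees list of \code{ape::phylo} trees on the same leaf set (e.g.
#'   one per genomic window, ordered along the locus)
#' @param normalized see \code{\link{rf_distance}}
#' @return square symmetric matrix
#' @export
rf_matrix <- function(trees, normalized = FALSE) {
  n <- length(trees)
  splits <- lapply(trees, tree_splits)
  M <- matrix(0, n, n)
  nm <- names(trees)
  if (!is.null(nm)) dimnames(M) <- list(nm, nm)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (!setequal(trees[[i]]$tip.label, trees[[j]]$tip.label)) {
      stop("trees must share an identical leaf set")
    }
    rf <- length(setdiff(splits[[i]], splits[[j]])) +
      length(setdiff(splits[[j]], splits[[i]]))
    if (normalized) rf <- rf / (2 * (length(trees[[i]]$tip.label) - 3))
    M[i, j] <- M[j, i] <- rf
  }
  M
}

#' Select windows in highest topological LD with an anchor window
#'
#' Orders windows by Robinson-Foulds distance to the anchor (by default the
#' right-most window, the one nearest the duplication) and returns the
#' anchor plus the \code{k} lowest. Ties are broken toward the window
#' genomically nearer the anchor (higher index), deterministically.
#'
#' @param rf square RF matrix over windows, ordered along the locus
#' @param k number of windows to select besides the anchor (default 1)
#' @param anchor anchor window index (default: last)
#' @return integer vector of selected window indices, sorted, including the
#'   anchor
#' @export
select_ld_windows <- function(rf, k = 1L, anchor = nrow(rf)) {
  n <- nrow(rf)
  if (n < 2L) stop("need >= 2 windows")
  if (k >= n) {
    warning("k >= number of windows; returning all windows")
    return(seq_len(n))
  }
  cand <- setdiff(seq_len(n), anchor)
  d <- rf[anchor, cand]
  prox <- abs(cand - anchor)
  ord <- cand[order(d, prox, cand)]
  sort(c(anchor, ord[seq_len(k)]))
}

# mean distance from each node down to its descendant tips (tips at 0),
# weighted by tip counts so it equals the true mean over all descendant tips
node_tip_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  h <- numeric(nn)
  cnt <- integer(nn)
  cnt[seq_len(ntip)] <- 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec_order <- rev(unique(tree$edge[, 1]))  # children before parents
  for (nd in rec_order) {
    es <- kids[[as.character(nd)]]
    ch <- tree$edge[es, 2]
    len <- tree$edge.length[es]
    cnt[nd] <- sum(cnt[ch])
    h[nd] <- sum(cnt[ch] * (h[ch] + len)) / cnt[nd]
  }
  h
}

#' Calibrate node ages by a fixed split time
#'
#' Scales approximately clock-like node depths into absolute ages: each
#' node's age is its mean root-to-tip-relative depth (mean distance to its
#' descendant tips) times \code{age / depth(calibration node)}, so the
#' calibration node's age is exact and ages are invariant to rescaling all
#' branch lengths. Typical calibrations at this locus are the
#' orangutan-human/chimpanzee/gorilla split at 18.13 Ma and the
#' human-chimpanzee split at 7.74 Ma.
#'
#' @param tree a rooted \code{ape::phylo} tree with branch lengths
#' @param clade character vector of tip labels whose MRCA is the
#'   calibration node
#' @param age age assigned to the calibration node (e.g. in Ma)
#' @param clock_tol warn when relative root-to-tip depth spread exceeds this
#'   (default 0.1)
#' @return list with \code{ages} (named vector over internal nodes),
#'   \code{tip_ages} (zeros), \code{calibration_node}, \code{rate} (depth
#'   units per age unit), and the input \code{tree}
#' @export
calibrate_node_ages <- function(tree, clade, age, clock_tol = 0.1) {
  stopifnot(age > 0)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!all(clade %in% tree$tip.label)) {
    stop("calibration clade tips absent from tree")
  }
  ntip <- length(tree$tip.label)
  cal_node <- if (length(clade) == 1L) {
    match(clade, tree$tip.label)
  } else {
    ape::getMRCA(tree, clade)
  }
  h <- node_tip_depths(tree)
  if (h[cal_node] <= 0) stop("calibration node has zero depth")
  root <- ntip + 1L
  tipd <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  if (mean(tipd) > 0 &&
      (max(tipd) - min(tipd)) / mean(tipd) > clock_tol) {
    warning(sprintf(
      "root-to-tip depths deviate from a clock by %.1f%% (tolerance %.0f%%)",
      100 * (max(tipd) - min(tipd)) / mean(tipd), 100 * clock_tol))
  }
  scale <- age / h[cal_node]
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  ages <- h[internal] * scale
  names(ages) <- as.character(internal)
  list(ages = ages,
       tip_ages = stats::setNames(numeric(ntip), tree$tip.label),
       calibration_node = cal_node,
       rate = 1 / scale,
       tree = tree)
}

#' Classical MDS ordination of an RF distance matrix
#'
#' Two-dimensional classical multidimensional scaling of the windowed-tree
#' RF matrix — the embedding in which distances of each window's tree to the
#' anchor window can be read along PC1/PC2.
#'
#' @param rf square RF matrix
#' @return matrix (windows x 2) of coordinates
#' @export
rf_mds <- function(rf) {
  stats::cmdscale(stats::as.dist(rf), k = min(2L, nrow(rf) - 1L))
}
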