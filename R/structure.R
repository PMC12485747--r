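#' Filter principal-bundle block decompositions
#'
#' Two filters applied in order: blocks present in exactly one haplotype are
#' removed (singleton rule), then blocks whose length falls strictly below
#' the \code{min_length_quantile} quantile of the remaining blocks' lengths
#' are removed. The resolved length threshold is recorded as the
#' \code{"min_length"} attribute of the result and reused verbatim when the
#' filter is applied again, mirroring how such thresholds are frozen as
#' concrete cutoffs once derived from a data set; this makes the filter
#' idempotent. An explicit \code{min_length} (bp) can be supplied instead of
#' the quantile.
#'
#' @param decomp data.frame with columns haplotype, rank (block order along
#'   the haplotype), block_id, orientation ("+"/"-"), length (bp)
#' @param min_length_quantile quantile of per-block lengths below which
#'   blocks are dropped (default 0.25)
#' @param drop_singletons remove blocks private to one haplotype
#'   (default TRUE)
#' @param min_length explicit length threshold in bp; overrides the quantile
#' @return the filtered data.frame, with attribute \code{min_length}; flags
#'   haplotypes left empty via the \code{empty_haplotypes} attribute
#' @export
filter_bundles <- function(decomp, min_length_quantile = 0.25,
                           drop_singletons = TRUE, min_length = NULL) {
  stopifnot(all(c("haplotype", "rank", "block_id", "orientation",
                  "length") %in% names(decomp)))
  if (min_length_quantile < 0 || min_length_quantile >= 1) {
    stop("min_length_quantile must lie in [0, 1)")
  }
  if (length(unique(decomp$haplotype)) < 2L) stop("need >= 2 haplotypes")
  x <- decomp
  if (drop_singletons) {
    carriers <- tapply(x$haplotype, x$block_id,
                       function(h) length(unique(h)))
    keep <- names(carriers)[carriers > 1L]
    x <- x[x$block_id %in% keep, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("all blocks removed by the singleton filter")
  if (is.null(min_length)) {
    min_length <- attr(decomp, "min_length")
  }
  if (is.null(min_length)) {
    block_len <- tapply(x$length, x$block_id, stats::median)
    min_length <- unname(stats::quantile(block_len, min_length_quantile,
                                         type = 7))
  }
  rep_len_of <- tapply(x$length, x$block_id, stats::median)
  x <- x[rep_len_of[as.character(x$block_id)] >= min_length, , drop = FALSE]
  if (nrow(x) == 0L) stop("all blocks removed by the length filter")
  empty <- setdiff(unique(decomp$haplotype), unique(x$haplotype))
  x <- x[order(x$haplotype, x$rank), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "min_length") <- min_length
  attr(x, "empty_haplotypes") <- empty
  x
}

#' Canonical structure signature of a block decomposition
#'
#' The signature is the ordered sequence of (block id, orientation) pairs,
#' canonicalized against strand: the reverse-complement reading (reversed
#' order, flipped orientations) maps to the same key, the canonical form
#' being the lexicographic minimum of the two readings. Haplotypes reported
#' on opposite strands therefore group together.
#'
#' @param block_id character/vector of block ids in haplotype order
#' @param orientation matching vector of "+"/"-"
#' @return a single canonical signature string
#' @export
structure_signature <- function(block_id, orientation) {
  stopifnot(length(block_id) == length(orientation),
            all(orientation %in% c("+", "-")))
  fwd <- paste(paste0(block_id, orientation), collapse = "|")
  flip <- ifelse(orientation == "-", "+", "-")
  rev_ <- paste(paste0(rev(block_id), rev(flip)), collapse = "|")
  min(fwd, rev_)
}

#' Group haplotypes into unique structures
#'
#' @param decomp a (filtered) block decomposition data.frame
#' @return list with \code{groups} (data.frame: signature, n_haplotypes,
#'   exemplar haplotype) and \code{assignment} (haplotype -> signature)
#' @export
group_structures <- function(decomp) {
  haps <- split(decomp, decomp$haplotype)
  sig <- vapply(haps, function(h)
    structure_signature(h$block_id[order(h$rank)],
                        h$orientation[order(h$rank)]), "")
  tab <- table(sig)
  exemplar <- vapply(names(tab), function(s) names(sig)[sig == s][1L], "")
  list(
    groups = data.frame(signature = names(tab),
                        n_haplotypes = as.integer(tab),
                        exemplar = exemplar,
                        stringsAsFactors = FALSE, row.names = NULL),
    assignment = sig
  )
}

#' Length-weighted Jaccard distance matrix between structures
#'
#' For two structures with per-block copy counts, the distance is
#' 1 - (sum over block ids of length x min(copies_A, copies_B)) /
#' (sum of length x max(copies_A, copies_B)). Identical structures are at
#' 0, structures with disjoint block sets at 1. Block lengths are the
#' median observed length per block id across the input.
#'
#' @param decomp a (filtered) block decomposition data.frame
#' @param structures optional \code{\link{group_structures}} result; grouped
#'   from \code{decomp} when NULL
#' @return list with \code{dist} (square symmetric matrix over unique
#'   structure signatures) and \code{multiplicity} (haplotypes per
#'   structure)
#' @export
jaccard_matrix <- function(decomp, structures = NULL) {
  if (is.null(structures)) structures <- group_structures(decomp)
  sigs <- structures$groups$signature
  block_len <- tapply(decomp$length, decomp$block_id, stats::median)
  counts <- lapply(structures$groups$exemplar, function(h) {
    d <- decomp[decomp$haplotype == h, ]
    table(d$block_id)
  })
  all_blocks <- names(block_len)
  cmat <- vapply(counts, function(tb) {
    v <- stats::setNames(numeric(length(all_blocks)), all_blocks)
    v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(all_blocks)))
  n <- length(sigs)
  D <- matrix(0, n, n, dimnames = list(sigs, sigs))
  w <- as.numeric(block_len)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      lo <- sum(w * pmin(cmat[, i], cmat[, j]))
      hi <- sum(w * pmax(cmat[, i], cmat[, j]))
      D[i, j] <- D[j, i] <- if (hi == 0) 0 else 1 - lo / hi
    }
  }
  list(dist = D,
       multiplicity = stats::setNames(structures$groups$n_haplotypes, sigs))
}

#' Cut a Jaccard dendrogram into summary structures
#'
#' Average-linkage hierarchical clustering of the structure distance matrix
#' cut at \code{h}, collapsing highly similar structures into summary
#' groups.
#'
#' @param jac a \code{\link{jaccard_matrix}} result (or a distance matrix)
#' @param h dendrogram cut height in Jaccard-distance units
#' @return integer vector: summary-group id per structure
#' @export
summary_structures <- function(jac, h = 0.2) {
  D <- if (is.list(jac)) jac$dist else jac
  if (nrow(D) == 1L) return(stats::setNames(1L, rownames(D)))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  stats::cutree(hc, h = h)
}
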