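# shared fixtures, all generated in code

# a compact locus + sector layout for fast depth tests: 400 kb control,
# sectors in the same relative arrangement as the real locus
small_sectors <- function() {
  data.frame(
    name   = c("alpha", "beta", "nsf_1", "nsf_2", "control"),
    contig = "chrS",
    start  = c(510000L, 460000L, 560000L, 620000L, 0L),
    end    = c(545000L, 490000L, 600000L, 660000L, 400000L),
    stringsAsFactors = FALSE
  )
}

small_config <- function(n = 40L, seed = 1L, n_tag_snps = 120L, ...) {
  sim_config(
    n_individuals = n,
    locus = list(contig = "chrS", start = 0L, end = 700000L),
    inversion_interior = list(contig = "chrS", start = 100000L,
                              end = 300000L),
    n_tag_snps = n_tag_snps,
    seed = seed,
    ...
  )
}

# deterministic per-test RNG sandbox
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

# brute-force inversion caller used as the independent oracle
brute_force_inversion <- function(g, min_call_fraction = 0.5) {
  labels <- c("H1/H1", "H1/H2", "H2/H2")
  vapply(seq_len(nrow(g)), function(i) {
    x <- g[i, ]
    use <- !is.na(x)
    if (sum(use) == 0 || sum(use) / length(x) < min_call_fraction) {
      return("no-call")
    }
    d <- sapply(0:2, function(e) sqrt(sum((x[use] - e)^2)))
    if (sum(d == min(d)) > 1L) return("no-call")
    labels[which.min(d)]
  }, "")
}

# tiny block-decomposition builder: blocks is a list
# haplotype -> data.frame(block_id, orientation, length)
make_decomp <- function(blocks) {
  do.call(rbind, lapply(names(blocks), function(h) {
    b <- blocks[[h]]
    data.frame(haplotype = h, rank = seq_len(nrow(b)), b,
               stringsAsFactors = FALSE)
  }))
}

# brute-force RF oracle: every edge of the (unrooted) tree bipartitions the
# tips; enumerate the parts by deleting the edge and flooding the graph
brute_force_splits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tips <- sort(tr$tip.label)
  n <- length(tips)
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    kept <- tr$edge[-e, , drop = FALSE]
    reach <- tr$edge[e, 2]
    repeat {
      grow <- kept[kept[, 1] %in% reach | kept[, 2] %in% reach, , drop = FALSE]
      new <- union(reach, c(grow))
      if (length(new) == length(reach)) break
      reach <- new
    }
    side <- tr$tip.label[intersect(reach, seq_len(n))]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

brute_force_rf <- function(t1, t2) {
  s1 <- brute_force_splits(t1)
  s2 <- brute_force_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

true_inversion_genotype <- function(truth) {
  h2 <- (parse_haplotype(truth$individuals$hap1)$inversion == "H2") +
    (parse_haplotype(truth$individuals$hap2)$inversion == "H2")
  c("H1/H1", "H1/H2", "H2/H2")[h2 + 1L]
}
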