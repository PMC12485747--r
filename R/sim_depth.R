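#' Simulate windowed read-depth tracks for a cohort
#'
#' Depth is simulated at the 100 bp tile level — the resolution the
#' copy-number estimator consumes — rather than per read. Each tile's read
#' count is Poisson with mean
#' \code{mean_coverage x (local true diploid CN / 2) x tile width}, stored as
#' per-base mean depth. Copy number is 2 everywhere except inside the
#' duplicon sectors, where it follows the individual's true haplotype pair;
#' the control region is copy-number invariant by construction.
#'
#' @param truth a \code{\link{draw_cohort}} result
#' @param sectors sector definitions (see \code{\link{sector_defs}}); must
#'   include a \code{control} sector
#' @param config the \code{\link{sim_config}} used
#' @return object of class \code{depth_sim}: list(tiles = data.frame(contig,
#'   start, end), depth = matrix tiles x samples of per-base depth)
#' @export
simulate_depth <- function(truth, sectors = sector_defs(), config) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!"control" %in% sectors$name) stop("sectors must include a control sector")
  if (config$mean_coverage <= 0) stop("mean_coverage must be positive")
  set.seed(config$seed + 2L)
  tile <- 100L
  loc <- config$locus
  starts <- seq.int(loc$start, loc$end - tile, by = tile)
  nt <- length(starts)
  ind <- truth$individuals
  n <- nrow(ind)

  # per-tile diploid CN baseline 2, sector tiles overridden per individual
  cn <- matrix(2, nrow = nt, ncol = n)
  sector_tiles <- function(name) {
    s <- sectors[sectors$name == name, ]
    if (nrow(s) == 0L) return(integer(0))
    which(starts >= s$start[1] & (starts + tile) <= s$end[1])
  }
  it_alpha <- sector_tiles("alpha")
  it_beta <- sector_tiles("beta")
  it_nsf1 <- sector_tiles("nsf_1")
  for (j in seq_len(n)) {
    cn[it_alpha, j] <- ind$alpha_cn[j]
    cn[it_beta, j] <- ind$beta_cn[j]
    cn[it_nsf1, j] <- 2 + (ind$nsf_cn[j] - 4)  # extras sit on one NSF copy
  }
  lambda <- config$mean_coverage * (cn / 2) * tile
  depth <- matrix(stats::rpois(nt * n, lambda) / tile, nrow = nt,
                  dimnames = list(NULL, ind$sample_id))
  structure(list(
    tiles = data.frame(contig = loc$contig, start = starts,
                       end = starts + tile),
    depth = depth
  ), class = "depth_sim")
}

#' Extract one sample's depth track as a bedGraph data.frame
#'
#' @param sim a \code{depth_sim}
#' @param sample sample id or column index
#' @return data.frame with columns contig, start, end, depth (bedGraph order)
#' @export
depth_bedgraph <- function(sim, sample) {
  stopifnot(inherits(sim, "depth_sim"))
  data.frame(sim$tiles, depth = sim$depth[, sample])
}

#' Write a bedGraph depth track
#'
#' Four columns (contig, start, end, value), 0-based half-open, no header.
#'
#' @param bg data.frame with columns contig, start, end, depth
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_bedgraph <- function(bg, path) {
  utils::write.table(bg[, c("contig", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a depth track (bedGraph or two-column TSV)
#'
#' bedGraph rows are (contig, start, end, depth), 0-based half-open.
#' Two-column input is (position, depth) with 1-based positions, expanded to
#' unit intervals.
#'
#' @param path input path
#' @return data.frame with columns contig, start, end, depth
#' @export
read_depth_track <- function(path) {
  first <- utils::read.table(path, sep = "\t", nrows = 1L)
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(first) >= 4L) {
    names(x)[1:4] <- c("contig", "start", "end", "depth")
    x[, 1:4]
  } else if (ncol(first) == 2L) {
    data.frame(contig = NA_character_, start = x[[1]] - 1L, end = x[[1]],
               depth = x[[2]])
  } else {
    stop("depth input must be 4-column bedGraph or 2-column (pos, depth) TSV")
  }
}
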