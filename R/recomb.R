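#' Recombination-scan configuration
#'
#' @param window non-overlapping window width in bp (default 10 kb)
#' @param min_run minimum adjacent outlier windows for a reassignment
#'   (default 2)
#' @param low,high reassignment percentiles of each genotype group's PC1
#'   (defaults 5 and 95); the same envelope defines window ambiguity
#' @param min_variants minimum biallelic variants for a window to be usable
#' @return list of class \code{scan_config}
#' @export
scan_config <- function(window = 10000L, min_run = 2L, low = 5, high = 95,
                        min_variants = 3L) {
  if (!(0 < low && low < high && high < 100)) {
    stop("need 0 < low < high < 100")
  }
  if (min_run < 1L) stop("min_run must be >= 1")
  structure(list(window = as.integer(window), min_run = as.integer(min_run),
                 low = low, high = high,
                 min_variants = as.integer(min_variants)),
            class = "scan_config")
}

GENOTYPE_GROUPS <- c("H1/H1", "H1/H2", "H2/H2")

#' Sliding-window PC1 scores across the inversion
#'
#' Runs a PCA on the centered genotype matrix of each non-overlapping window
#' and returns every sample's PC1 score. Because the sign of a principal
#' component is arbitrary, each window's PC1 is oriented so that the H2/H2
#' group mean is at least the H1/H1 group mean (falling back to the
#' heterozygote group when a homozygote class is absent); this makes runs of
#' scores comparable across windows. Windows with too few variants or zero
#' variance are flagged ambiguous.
#'
#' @param snps list with \code{genotypes} (samples x sites, 0/1/2) and
#'   \code{positions} (bp), e.g. \code{\link{simulate_inversion_snps}} or
#'   \code{\link{vcf_genotype_matrix}} output
#' @param calls inversion calls (\code{\link{genotype_inversion}} output)
#'   aligned to the rows of \code{snps$genotypes} by sample id
#' @param config a \code{\link{scan_config}}
#' @param region analyzed region, list(start, end); defaults to the span of
#'   the sites
#' @return object of class \code{windowed_pca}: list(windows =
#'   data.frame(start, end, n_variants, ambiguous), scores (samples x
#'   windows), genotype (per-sample call))
#' @export
windowed_pc1 <- function(snps, calls, config = scan_config(), region = NULL) {
  g <- snps$genotypes
  pos <- snps$positions
  if (is.null(region)) {
    region <- list(start = min(pos) - (min(pos) %% config$window),
                   end = max(pos) + 1L)
  }
  starts <- seq.int(region$start, region$end - config$window,
                    by = config$window)
  nw <- length(starts)
  genotype <- calls$genotype[match(rownames(g), calls$sample)]
  scores <- matrix(NA_real_, nrow = nrow(g), ncol = nw,
                   dimnames = list(rownames(g), NULL))
  nvar <- integer(nw)
  amb <- logical(nw)
  for (k in seq_len(nw)) {
    in_win <- pos >= starts[k] & pos < starts[k] + config$window
    sites <- which(in_win)
    gw <- g[, sites, drop = FALSE]
    gw <- gw[, apply(gw, 2L, function(col) stats::var(col, na.rm = TRUE) > 0),
             drop = FALSE]
    nvar[k] <- ncol(gw)
    if (ncol(gw) < config$min_variants) {
      amb[k] <- TRUE
      next
    }
    gw[is.na(gw)] <- 0L
    pc1 <- stats::prcomp(gw, center = TRUE, scale. = FALSE)$x[, 1L]
    # orient: higher PC1 = more H2-like
    lo <- mean(pc1[genotype == "H1/H1"])
    hi <- mean(pc1[genotype == "H2/H2"])
    if (!is.finite(lo)) lo <- mean(pc1[genotype == "H1/H2"])
    if (!is.finite(hi)) hi <- mean(pc1[genotype == "H1/H2"])
    if (is.finite(lo) && is.finite(hi) && hi < lo) pc1 <- -pc1
    scores[, k] <- pc1
  }
  structure(list(
    windows = data.frame(start = starts, end = starts + config$window,
                         n_variants = nvar, ambiguous = amb),
    scores = scores,
    genotype = genotype
  ), class = "windowed_pca")
}

#' Per-window, per-genotype PC1 statistics
#'
#' Mean, median and the configured low/high percentiles of PC1 for each
#' inversion genotype group in every usable window, computed over samples
#' with confident upstream calls.
#'
#' @param scan a \code{\link{windowed_pc1}} result
#' @param config a \code{\link{scan_config}}
#' @return list of (windows x groups) matrices: mean, median, qlow, qhigh
#' @export
group_pc1_stats <- function(scan, config = scan_config()) {
  nw <- nrow(scan$windows)
  mk <- function() matrix(NA_real_, nrow = nw, ncol = 3L,
                          dimnames = list(NULL, GENOTYPE_GROUPS))
  out <- list(mean = mk(), median = mk(), qlow = mk(), qhigh = mk())
  probs <- c(config$low, config$high) / 100
  for (grp in GENOTYPE_GROUPS) {
    rows <- which(scan$genotype == grp)
    if (length(rows) == 0L) next
    sc <- scan$scores[rows, , drop = FALSE]
    out$mean[, grp] <- colMeans(sc)
    out$median[, grp] <- apply(sc, 2L, stats::median)
    q <- apply(sc, 2L, stats::quantile, probs = probs, na.rm = FALSE,
               names = FALSE)
    out$qlow[, grp] <- q[1L, ]
    out$qhigh[, grp] <- q[2L, ]
  }
  out
}

#' Flag windows whose genotype-group PC1 envelopes overlap
#'
#' A window is ambiguous when any two genotype groups'
#' [low, high]-percentile PC1 intervals intersect — such windows carry no
#' reliable group separation and are excluded from reassignment.
#'
#' @param scan a \code{\link{windowed_pc1}} result
#' @param stats \code{\link{group_pc1_stats}} output
#' @return the scan with \code{windows$ambiguous} updated
#' @export
flag_ambiguous_windows <- function(scan, stats) {
  nw <- nrow(scan$windows)
  for (k in seq_len(nw)) {
    if (scan$windows$ambiguous[k]) next
    lo <- stats$qlow[k, ]; hi <- stats$qhigh[k, ]
    grps <- which(is.finite(lo) & is.finite(hi))
    if (length(grps) < 2L) {
      scan$windows$ambiguous[k] <- TRUE
      next
    }
    for (a in grps) for (b in grps) {
      if (a < b && lo[a] <= hi[b] && lo[b] <= hi[a]) {
        scan$windows$ambiguous[k] <- TRUE
      }
    }
  }
  scan
}

# per-sample, per-window candidate reassignment target ("" = concordant,
# NA = ambiguous window)
outlier_targets <- function(scan, stats, config) {
  nw <- nrow(scan$windows)
  n <- nrow(scan$scores)
  targ <- matrix("", nrow = n, ncol = nw,
                 dimnames = list(rownames(scan$scores), NULL))
  targ[, scan$windows$ambiguous] <- NA_character_
  usable <- which(!scan$windows$ambiguous)
  for (i in seq_len(n)) {
    g <- scan$genotype[i]
    if (is.na(g) || !g %in% GENOTYPE_GROUPS) {
      targ[i, ] <- NA_character_
      next
    }
    s <- scan$scores[i, usable]
    if (g == "H1/H2") {
      below <- s < stats$qlow[usable, "H1/H2"]
      above <- s > stats$qhigh[usable, "H1/H2"]
      targ[i, usable[below]] <- "H1/H1"
      targ[i, usable[above]] <- "H2/H2"
    } else if (g == "H1/H1") {
      # crossing the heterozygote envelope's near (low) boundary
      out <- s > stats$qhigh[usable, "H1/H1"] &
        s >= stats$qlow[usable, "H1/H2"]
      targ[i, usable[out]] <- "H1/H2"
    } else {
      out <- s < stats$qlow[usable, "H2/H2"] &
        s <= stats$qhigh[usable, "H1/H2"]
      targ[i, usable[out]] <- "H1/H2"
    }
  }
  targ
}

#' Detect runs of outlier windows and reassign their genotype
#'
#' A sample's window is a candidate outlier when its PC1 exits its own
#' genotype group's [low, high]-percentile envelope toward another group
#' (heterozygotes below the 5th percentile toward H1/H1, above the 95th
#' toward H2/H2; homozygotes crossing the heterozygote envelope's near
#' boundary). Only maximal runs of at least \code{min_run} adjacent
#' candidate windows with the same target are reassigned; runs separated by
#' a single ambiguous window are merged. A run is confirmed only if its mean
#' PC1 is closer to the target group's per-window medians than to the
#' sample's own group — an isolated percentile excursion that stays near its
#' own group is noise, not recombination.
#'
#' @param scan a \code{\link{windowed_pc1}} result, ambiguity-flagged
#' @param stats \code{\link{group_pc1_stats}} output
#' @param config a \code{\link{scan_config}}
#' @return data.frame of reassigned runs: sample, win_from, win_to (window
#'   indices), start, end (bp), original, target, n_windows
#' @export
detect_outlier_runs <- function(scan, stats, config = scan_config()) {
  targ <- outlier_targets(scan, stats, config)
  runs <- list()
  nw <- nrow(scan$windows)
  for (i in seq_len(nrow(targ))) {
    v <- targ[i, ]
    k <- 1L
    while (k <= nw) {
      if (is.na(v[k]) || v[k] == "") {
        k <- k + 1L
        next
      }
      tgt <- v[k]
      # extend run; a single intervening ambiguous window does not break it
      j <- k
      last_hit <- k
      while (j < nw) {
        nxt <- v[j + 1L]
        if (identical(nxt, tgt)) {
          j <- j + 1L
          last_hit <- j
        } else if (is.na(nxt) && j + 1L < nw && identical(v[j + 2L], tgt) &&
                   !is.na(v[j + 2L])) {
          j <- j + 2L
          last_hit <- j
        } else {
          break
        }
      }
      wins <- which(!is.na(v[k:last_hit]) & v[k:last_hit] == tgt) + k - 1L
      if (length(wins) >= config$min_run) {
        s <- scan$scores[i, wins]
        own <- scan$genotype[i]
        d_own <- mean(abs(s - stats$median[wins, own]))
        d_tgt <- mean(abs(s - stats$median[wins, tgt]))
        if (is.finite(d_own) && is.finite(d_tgt) && d_tgt < d_own) {
          runs[[length(runs) + 1L]] <- data.frame(
            sample = rownames(targ)[i],
            win_from = k, win_to = last_hit,
            start = scan$windows$start[k], end = scan$windows$end[last_hit],
            original = own, target = tgt, n_windows = length(wins),
            stringsAsFactors = FALSE)
        }
      }
      k <- last_hit + 1L
    }
  }
  if (length(runs) == 0L) {
    return(data.frame(sample = character(), win_from = integer(),
                      win_to = integer(), start = integer(),
                      end = integer(), original = character(),
                      target = character(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, runs)
}

#' Classify reassigned runs as single or double recombination events
#'
#' A run flanked on both sides by at least one non-ambiguous window
#' concordant with the sample's original genotype is a double event (an
#' interior tract produced by two crossovers or long gene conversion); a run
#' reaching either boundary of the analyzed region is a single event.
#'
#' @param runs \code{\link{detect_outlier_runs}} output
#' @param scan the ambiguity-flagged \code{\link{windowed_pc1}} result
#' @param populations optional named vector (sample -> population label)
#' @return data.frame of events: sample, start, end, length_bp, class
#'   ("single"/"double"), from, to, population
#' @export
classify_events <- function(runs, scan, populations = NULL) {
  usable <- which(!scan$windows$ambiguous)
  lo_bound <- if (length(usable)) min(usable) else 1L
  hi_bound <- if (length(usable)) max(usable) else nrow(scan$windows)
  ev <- lapply(seq_len(nrow(runs)), function(r) {
    x <- runs[r, ]
    at_edge <- x$win_from <= lo_bound || x$win_to >= hi_bound
    data.frame(
      sample = x$sample, start = x$start, end = x$end,
      length_bp = x$end - x$start,
      class = if (at_edge) "single" else "double",
      from = x$original, to = x$target,
      population = if (!is.null(populations))
        unname(populations[x$sample]) else NA_character_,
      stringsAsFactors = FALSE)
  })
  if (length(ev) == 0L) {
    return(data.frame(sample = character(), start = integer(),
                      end = integer(), length_bp = integer(),
                      class = character(), from = character(),
                      to = character(), population = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, ev)
}

#' Full recombination scan
#'
#' Convenience wrapper: windowed PC1, group statistics, ambiguity flagging,
#' outlier-run detection and event classification in one call.
#'
#' @inheritParams windowed_pc1
#' @param populations optional named vector (sample -> population label)
#' @return list(scan, stats, runs, events)
#' @export
scan_recomb <- function(snps, calls, config = scan_config(), region = NULL,
                        populations = NULL) {
  scan <- windowed_pc1(snps, calls, config, region)
  stats <- group_pc1_stats(scan, config)
  scan <- flag_ambiguous_windows(scan, stats)
  runs <- detect_outlier_runs(scan, stats, config)
  events <- classify_events(runs, scan, populations)
  list(scan = scan, stats = stats, runs = runs, events = events)
}
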