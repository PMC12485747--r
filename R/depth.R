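#' Copy-number estimation configuration
#'
#' @param window_size sliding-window width in bp (default 1000)
#' @param step window step in bp (default 100)
#' @param cn_max_kansl1 QC cap on KANSL1 duplicon (alpha/beta) copy number
#' @param cn_max_nsf QC cap on summed NSF copy number
#' @param stat control normalization statistic, "mean" or "median"
#' @param min_control_windows minimum usable control windows (default 100)
#' @param min_sector_windows minimum windows overlapping a sector (default 10)
#' @return list of class \code{depth_config}
#' @export
depth_config <- function(window_size = 1000L, step = 100L,
                         cn_max_kansl1 = 20, cn_max_nsf = 50,
                         stat = c("mean", "median"),
                         min_control_windows = 100L,
                         min_sector_windows = 10L) {
  stat <- match.arg(stat)
  if (step > window_size) stop("step must not exceed window_size")
  if (cn_max_kansl1 <= 0 || cn_max_nsf <= 0) stop("CN caps must be positive")
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 cn_max_kansl1 = cn_max_kansl1, cn_max_nsf = cn_max_nsf,
                 stat = stat,
                 min_control_windows = as.integer(min_control_windows),
                 min_sector_windows = as.integer(min_sector_windows)),
            class = "depth_config")
}

#' Sliding-window mean depth
#'
#' Averages per-base depth in \code{window_size} bp windows advancing by
#' \code{step} bp across \code{region}; trailing partial windows are
#' dropped. Input is a bedGraph-style data.frame (contig, start, end, depth,
#' 0-based half-open). When the input is tiled at a width dividing both the
#' window and the step (as the simulator emits), windows are aggregated
#' directly from tiles; otherwise depth is expanded per base. Windows
#' touching any uncovered base are marked missing and excluded from sector
#' means downstream.
#'
#' @param track depth data.frame (see \code{\link{read_depth_track}})
#' @param config a \code{\link{depth_config}}
#' @param region list(contig, start, end), 0-based half-open
#' @return object of class \code{depth_track}: list(windows =
#'   data.frame(start, end, raw, norm), contig, control_stat)
#' @export
window_depth <- function(track, config = depth_config(), region) {
  w <- config$window_size; s <- config$step
  n_win <- (region$end - region$start - w) %/% s + 1L
  if (n_win < 1L) stop("region shorter than one window")
  win_start <- region$start + s * (0:(n_win - 1L))

  widths <- track$end - track$start
  tile <- widths[1]
  tiled <- all(widths == tile) && w %% tile == 0L && s %% tile == 0L &&
    all((track$start - region$start) %% tile == 0L)
  if (tiled) {
    nt <- (region$end - region$start) %/% tile
    tile_depth <- rep(NA_real_, nt)
    idx <- (track$start - region$start) %/% tile + 1L
    keep <- idx >= 1L & idx <= nt
    tile_depth[idx[keep]] <- track$depth[keep]
    per_win <- w %/% tile
    cs <- c(0, cumsum(ifelse(is.na(tile_depth), 0, tile_depth)))
    csn <- c(0, cumsum(is.na(tile_depth)))
    first <- (win_start - region$start) %/% tile
    last <- first + per_win
    raw <- rep(NA_real_, n_win)
    ok <- last <= nt & (csn[last + 1L] - csn[first + 1L]) == 0L
    raw[ok] <- (cs[last[ok] + 1L] - cs[first[ok] + 1L]) / per_win
  } else {
    span <- region$end - region$start
    if (span > 2e6) {
      stop("non-tiled depth input over a region > 2 Mb; pre-tile upstream")
    }
    base <- rep(NA_real_, span)
    for (r in seq_len(nrow(track))) {
      a <- max(track$start[r], region$start) - region$start
      b <- min(track$end[r], region$end) - region$start
      if (b > a) base[(a + 1L):b] <- track$depth[r]
    }
    cs <- c(0, cumsum(ifelse(is.na(base), 0, base)))
    csn <- c(0, cumsum(is.na(base)))
    first <- win_start - region$start
    last <- first + w
    raw <- rep(NA_real_, n_win)
    ok <- (csn[last + 1L] - csn[first + 1L]) == 0L
    raw[ok] <- (cs[last[ok] + 1L] - cs[first[ok] + 1L]) / w
  }
  structure(list(
    windows = data.frame(start = win_start, end = win_start + w,
                         raw = raw, norm = NA_real_),
    contig = region$contig,
    control_stat = NULL
  ), class = "depth_track")
}

#' Normalize a depth track to a copy-number-invariant control region
#'
#' Each window's normalized depth is its raw mean divided by the mean (or
#' median) raw depth of windows falling entirely inside the control region,
#' so normalized depth 1.0 corresponds to diploid copy number 2.
#'
#' @param track a \code{\link{window_depth}} result
#' @param control control sector: list or one-row data.frame with start, end
#' @param config a \code{\link{depth_config}}
#' @return the track with \code{norm} filled and \code{control_stat} recorded
#' @export
normalize_depth <- function(track, control, config = depth_config()) {
  wd <- track$windows
  inside <- wd$start >= control$start & wd$end <= control$end & !is.na(wd$raw)
  if (sum(inside) < config$min_control_windows) {
    stop("only ", sum(inside), " usable control windows (need >= ",
         config$min_control_windows, ")")
  }
  stat <- if (config$stat == "mean") mean(wd$raw[inside]) else
    stats::median(wd$raw[inside])
  if (!is.finite(stat) || stat <= 0) stop("control depth statistic <= 0")
  track$windows$norm <- wd$raw / stat
  track$control_stat <- stat
  track
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Diploid copy number of a duplicon sector
#'
#' Continuous CN is twice the mean normalized depth of windows overlapping
#' the sector (normalized depth 1 = diploid CN 2); the integer call rounds
#' half away from zero. QC fails when the estimate exceeds \code{cap}.
#'
#' @param track a normalized \code{depth_track}
#' @param sector list/one-row data.frame with name, start, end
#' @param config a \code{\link{depth_config}}
#' @param cap QC cap (defaults to the KANSL1 cap in \code{config})
#' @return one-row data.frame: sector, cn_continuous, cn_call, n_windows,
#'   qc ("pass"/"fail"/"no-call"), reason
#' @export
sector_cn <- function(track, sector, config = depth_config(),
                      cap = config$cn_max_kansl1) {
  if (is.null(track$control_stat)) stop("track is not normalized")
  wd <- track$windows
  ov <- wd$start < sector$end & wd$end > sector$start & !is.na(wd$norm)
  nm <- if (!is.null(sector$name)) sector$name else "sector"
  if (sum(ov) < config$min_sector_windows) {
    return(data.frame(sector = nm, cn_continuous = NA_real_,
                      cn_call = NA_integer_, n_windows = sum(ov),
                      qc = "no-call",
                      reason = "too few overlapping windows",
                      stringsAsFactors = FALSE))
  }
  cn <- 2 * mean(wd$norm[ov])
  fail <- cn > cap
  data.frame(sector = nm, cn_continuous = cn,
             cn_call = as.integer(round_half_away(cn)),
             n_windows = sum(ov),
             qc = if (fail) "fail" else "pass",
             reason = if (fail) sprintf("CN %.1f exceeds cap %g", cn, cap)
                      else "",
             stringsAsFactors = FALSE)
}

#' Summed NSF copy number over the two reference NSF regions
#'
#' The reference assembly carries two NSF copies, so diploid NSF copy number
#' is twice the sum of the mean normalized depths over the two target
#' regions (baseline 4 when both sit at normalized depth 1).
#'
#' @param track a normalized \code{depth_track}
#' @param nsf_1,nsf_2 the two NSF sector definitions
#' @param config a \code{\link{depth_config}}
#' @return one-row data.frame as in \code{\link{sector_cn}}
#' @export
nsf_cn <- function(track, nsf_1, nsf_2, config = depth_config()) {
  parts <- lapply(list(nsf_1, nsf_2), function(s)
    sector_cn(track, s, config, cap = Inf))
  if (any(vapply(parts, function(p) p$qc == "no-call", TRUE))) {
    return(data.frame(sector = "nsf", cn_continuous = NA_real_,
                      cn_call = NA_integer_, n_windows = 0L, qc = "no-call",
                      reason = "an NSF target region is unusable",
                      stringsAsFactors = FALSE))
  }
  cn <- parts[[1]]$cn_continuous + parts[[2]]$cn_continuous
  fail <- cn > config$cn_max_nsf
  data.frame(sector = "nsf", cn_continuous = cn,
             cn_call = as.integer(round_half_away(cn)),
             n_windows = parts[[1]]$n_windows + parts[[2]]$n_windows,
             qc = if (fail) "fail" else "pass",
             reason = if (fail) sprintf("CN %.1f exceeds cap %g", cn,
                                        config$cn_max_nsf) else "",
             stringsAsFactors = FALSE)
}

#' Copy-number estimates for a whole simulated cohort
#'
#' Runs window averaging, control normalization and sector CN estimation for
#' every sample of a \code{\link{simulate_depth}} result.
#'
#' @param sim a \code{depth_sim}
#' @param sectors sector definitions (see \code{\link{sector_defs}})
#' @param config a \code{\link{depth_config}}
#' @param region region to window (default: the span of the tiles)
#' @return data.frame with one row per sample x sector
#' @export
estimate_cohort_cn <- function(sim, sectors = sector_defs(),
                               config = depth_config(), region = NULL) {
  stopifnot(inherits(sim, "depth_sim"))
  if (is.null(region)) {
    region <- list(contig = sim$tiles$contig[1],
                   start = min(sim$tiles$start), end = max(sim$tiles$end))
  }
  ctrl <- as.list(sectors[sectors$name == "control", ])
  alpha <- as.list(sectors[sectors$name == "alpha", ])
  beta <- as.list(sectors[sectors$name == "beta", ])
  nsf1 <- as.list(sectors[sectors$name == "nsf_1", ])
  nsf2 <- as.list(sectors[sectors$name == "nsf_2", ])
  out <- lapply(colnames(sim$depth), function(id) {
    bg <- data.frame(sim$tiles, depth = sim$depth[, id])
    tr <- window_depth(bg, config, region)
    tr <- normalize_depth(tr, ctrl, config)
    est <- rbind(sector_cn(tr, alpha, config),
                 sector_cn(tr, beta, config),
                 nsf_cn(tr, nsf1, nsf2, config))
    cbind(sample = id, est, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
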