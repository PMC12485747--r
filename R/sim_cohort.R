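#' Draw a synthetic cohort with known structural-haplotype truth
#'
#' Each individual receives two structural haplotypes drawn i.i.d. from the
#' configured frequencies, or — when a temporal trajectory is configured —
#' from the multinomial-logit model evaluated at the individual's age, with
#' ages uniform on the trajectory's time range. True diploid sector copy
#' numbers follow from the haplotype pair (baseline 2 per duplicon sector,
#' plus one per extra duplicon copy; NSF baseline 4 plus configured extras).
#'
#' @param config a \code{\link{sim_config}}
#' @return object of class \code{cohort_truth}: list with
#'   \code{individuals} (data.frame: sample_id, hap1, hap2, age_bp,
#'   population, alpha_cn, beta_cn, nsf_cn), \code{tracts} (the implanted
#'   recombination tracts), and \code{config}
#' @export
draw_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("S%04d", seq_len(n))

  if (is.null(config$trajectory)) {
    labels <- names(config$haplotype_freqs)
    haps <- matrix(sample(labels, 2L * n, replace = TRUE,
                          prob = config$haplotype_freqs),
                   ncol = 2L)
    ages <- rep(NA_real_, n)
  } else {
    tr <- config$trajectory
    ages <- round(stats::runif(n, tr$t_range[1], tr$t_range[2]))
    pr <- trajectory_frequencies(tr, ages)
    labels <- colnames(pr)
    haps <- matrix("", nrow = n, ncol = 2L)
    for (i in seq_len(n)) {
      haps[i, ] <- sample(labels, 2L, replace = TRUE, prob = pr[i, ])
    }
    # collapsed "2+" categories materialize as concrete 2-copy haplotypes
    haps[] <- sub("\\+$", "", haps)
  }

  cn <- t(apply(haps, 1L, function(h) expected_cn(h[1], h[2])))
  nsf <- 4L + rep_len(config$nsf_extra_copies, n)
  individuals <- data.frame(
    sample_id = ids,
    hap1 = haps[, 1L], hap2 = haps[, 2L],
    age_bp = ages,
    population = "SIM",
    alpha_cn = cn[, "alpha"], beta_cn = cn[, "beta"], nsf_cn = nsf,
    stringsAsFactors = FALSE
  )
  structure(list(individuals = individuals,
                 tracts = config$recomb_tracts,
                 config = config),
            class = "cohort_truth")
}

#' Draw parent-offspring trios with Mendelian transmission
#'
#' Parents are drawn i.i.d. from the configured haplotype frequencies; each
#' child receives one haplotype from each parent uniformly at random (no
#' recombination between structural haplotypes). Used to validate the
#' genotyping pipeline by Mendelian consistency.
#'
#' @param n_trios number of trios
#' @param config a \code{\link{sim_config}}; its \code{n_individuals} is
#'   ignored in favour of \code{3 * n_trios}
#' @return list with \code{truth} (a \code{cohort_truth} over father,
#'   mother, child of each trio) and \code{pedigree} (data.frame: child,
#'   father, mother sample ids)
#' @export
draw_trios <- function(n_trios, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  labels <- names(config$haplotype_freqs)
  parents <- matrix(sample(labels, 4L * n_trios, replace = TRUE,
                           prob = config$haplotype_freqs),
                    ncol = 4L)  # father hap1/2, mother hap1/2
  pick_f <- sample(1:2, n_trios, replace = TRUE)
  pick_m <- sample(1:2, n_trios, replace = TRUE)
  ids <- sprintf("T%03d_%s", rep(seq_len(n_trios), each = 3L),
                 c("F", "M", "C"))
  haps <- matrix("", nrow = 3L * n_trios, ncol = 2L)
  for (t in seq_len(n_trios)) {
    r <- (t - 1L) * 3L
    haps[r + 1L, ] <- parents[t, 1:2]
    haps[r + 2L, ] <- parents[t, 3:4]
    haps[r + 3L, ] <- c(parents[t, pick_f[t]], parents[t, 2L + pick_m[t]])
  }
  cn <- t(apply(haps, 1L, function(h) expected_cn(h[1], h[2])))
  individuals <- data.frame(
    sample_id = ids, hap1 = haps[, 1L], hap2 = haps[, 2L],
    age_bp = NA_real_, population = "SIM",
    alpha_cn = cn[, "alpha"], beta_cn = cn[, "beta"],
    nsf_cn = 4L + rep_len(config$nsf_extra_copies, 3L * n_trios),
    stringsAsFactors = FALSE
  )
  cfg <- config
  cfg$n_individuals <- 3L * n_trios
  truth <- structure(list(individuals = individuals, tracts = list(),
                          config = cfg), class = "cohort_truth")
  ped <- data.frame(child = ids[seq(3L, length(ids), 3L)],
                    father = ids[seq(1L, length(ids), 3L)],
                    mother = ids[seq(2L, length(ids), 3L)],
                    stringsAsFactors = FALSE)
  list(truth = truth, pedigree = ped)
}

#' Category frequencies under a two-endpoint trajectory
#'
#' Log-odds relative to the first category are interpolated linearly in time
#' between the past and present endpoint frequencies, i.e. the trajectory is
#' exactly a multinomial-logit model with one linear time term per category.
#'
#' @param trajectory list(t_range, freq_present, freq_past)
#' @param ages_bp numeric vector of sample ages in years BP
#' @return matrix (length(ages_bp) x categories) of frequencies, rows sum to 1
#' @export
trajectory_frequencies <- function(trajectory, ages_bp) {
  par <- trajectory_true_params(trajectory)
  s <- -ages_bp / 1000  # kiloyears, oriented toward the present
  eta <- cbind(0, outer(s, par$slope) +
                    matrix(par$intercept, length(s), length(par$intercept),
                           byrow = TRUE))
  p <- exp(eta - apply(eta, 1L, max))
  p <- p / rowSums(p)
  colnames(p) <- c(par$reference, names(par$intercept))
  p
}

#' True multinomial-logit parameters implied by a trajectory
#'
#' Time enters in kiloyears BP oriented so that a positive slope means the
#' category increases toward the present; the first category is the
#' reference. These are the ground-truth coefficients that
#' \code{\link{fit_multinomial}} should recover from simulated cohorts.
#'
#' @param trajectory list(t_range, freq_present, freq_past)
#' @return list(reference, intercept, slope) — intercept and slope are named
#'   vectors over the non-reference categories
#' @export
trajectory_true_params <- function(trajectory) {
  fp <- trajectory$freq_present
  fq <- trajectory$freq_past
  stopifnot(identical(names(fp), names(fq)))
  ref <- names(fp)[1L]
  rest <- names(fp)[-1L]
  a <- log(fp[rest] / fp[[ref]])                  # logits at s = 0 (present)
  L_past <- log(fq[rest] / fq[[ref]])
  s_past <- -trajectory$t_range[2] / 1000
  b <- (a - L_past) / (-s_past)
  list(reference = ref, intercept = a, slope = b)
}

#' Aged haplotype observations from a cohort
#'
#' Unrolls a cohort into one row per haplotype (two per individual) with the
#' simplified category label and the sample's age — the input format of the
#' trajectory model.
#'
#' @param truth a \code{cohort_truth} with simulated ages
#' @return data.frame with columns sample_id, category, age_bp, population
#' @export
cohort_haplotype_obs <- function(truth) {
  ind <- truth$individuals
  if (all(is.na(ind$age_bp))) stop("cohort was simulated without a trajectory")
  data.frame(
    sample_id = rep(ind$sample_id, 2L),
    category = simplify_haplotype(c(ind$hap1, ind$hap2)),
    age_bp = rep(ind$age_bp, 2L),
    population = rep(ind$population, 2L),
    stringsAsFactors = FALSE
  )
}

#' Write cohort truth tables
#'
#' Emits the sample metadata TSV (sample_id, population, age_bp) and the
#' truth TSV (haplotype pair and true sector copy numbers).
#'
#' @param truth a \code{cohort_truth}
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_cohort_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- truth$individuals[, c("sample_id", "population", "age_bp")]
  meta_path <- file.path(dir, "samples.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$individuals, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(meta_path, truth_path))
}
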