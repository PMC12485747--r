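#' Fit a multinomial logistic model of haplotype category vs time
#'
#' Maximum-likelihood fit of a multinomial logit with a linear time
#' predictor: for non-reference category k,
#' log(p_k / p_ref) = a_k + b_k s, where s is time in kiloyears BP oriented
#' toward the present (s = -age_bp/1000), so a positive slope means the
#' category has increased toward the present. The solver is a damped Newton
#' iteration on the full log-likelihood with analytic gradient and Hessian;
#' convergence is declared when the log-likelihood improves by less than
#' \code{tol} (default 1e-8) and non-convergence within \code{max_iter}
#' iterations is reported on the model object, never silently truncated.
#'
#' Each haplotype observation (two per diploid individual) contributes one
#' multinomial draw. Categories named in \code{categories} but absent from
#' the data are fixed at frequency 0 with a warning (complete-separation
#' guard); a data set containing a single category is reported as separated
#' with no finite estimates.
#'
#' @param obs data.frame with columns \code{category} and \code{age_bp}
#'   (years before present, >= 0)
#' @param categories category levels (default: the four simplified
#'   architectures, restricted to those observed)
#' @param reference reference category (default: first level)
#' @param max_iter,tol Newton iteration controls
#' @return object of class \code{trajectory_model}: list with
#'   \code{coefficients} ((K-1) x 2 matrix, columns intercept/slope),
#'   \code{vcov}, \code{se}, \code{logLik}, \code{converged},
#'   \code{separation}, \code{categories}, \code{reference},
#'   \code{dropped} (categories fixed at 0), \code{n}
#' @export
fit_multinomial <- function(obs, categories = NULL, reference = NULL,
                            max_iter = 100L, tol = 1e-8) {
  stopifnot(all(c("category", "age_bp") %in% names(obs)))
  if (nrow(obs) < 10L) stop("need >= 10 observations")
  if (any(!is.finite(obs$age_bp))) stop("ages must be finite")
  if (is.null(categories)) {
    categories <- intersect(haplotype_categories(), unique(obs$category))
    if (length(categories) == 0L) categories <- sort(unique(obs$category))
  }
  dropped <- setdiff(categories, unique(obs$category))
  if (length(dropped) > 0L) {
    warning("categories absent from data fixed at frequency 0: ",
            paste(dropped, collapse = ", "))
  }
  lev <- setdiff(categories, dropped)
  if (!all(obs$category %in% lev)) {
    stop("observations outside the configured categories: ",
         paste(setdiff(unique(obs$category), lev), collapse = ", "))
  }
  if (is.null(reference)) reference <- lev[1L]
  stopifnot(reference %in% lev)
  lev <- c(reference, setdiff(lev, reference))
  K <- length(lev)
  base <- list(categories = lev, reference = reference, dropped = dropped,
               n = nrow(obs))
  if (K < 2L) {
    return(structure(c(base, list(
      coefficients = NULL, vcov = NULL, se = NULL, logLik = 0,
      converged = FALSE, separation = TRUE)), class = "trajectory_model"))
  }

  y <- match(obs$category, lev)            # 1 = reference
  s <- -obs$age_bp / 1000                  # kiloyears, toward present
  if (stats::sd(s) == 0) {
    # no time information: slopes are exactly 0 and the intercepts are the
    # saturated log-odds of the category counts at the common covariate
    counts <- tabulate(y, nbins = K)
    if (any(counts == 0L)) {
      return(structure(c(base, list(
        coefficients = NULL, vcov = NULL, se = NULL, logLik = NA_real_,
        converged = FALSE, separation = TRUE)), class = "trajectory_model"))
    }
    eta_at_s <- log(counts[-1L] / counts[1L])
    theta <- cbind(intercept = eta_at_s, slope = 0)
    rownames(theta) <- lev[-1L]
    ll <- sum(counts * log(counts / sum(counts)))
    return(structure(c(base, list(
      coefficients = theta, vcov = NULL, se = NULL, logLik = ll,
      converged = TRUE, separation = FALSE)), class = "trajectory_model"))
  }
  X <- cbind(1, s)
  n <- length(y)
  P <- 2L * (K - 1L)                       # free parameters
  Y <- matrix(0, n, K - 1L)
  for (k in 2:K) Y[y == k, k - 1L] <- 1

  probs <- function(theta) {               # theta: (K-1) x 2
    eta <- X %*% t(theta)                  # n x (K-1)
    m <- pmax(apply(eta, 1L, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    list(p = exp(eta - m) / denom, p_ref = exp(-m) / denom)
  }
  loglik <- function(theta) {
    pr <- probs(theta)
    full <- cbind(pr$p_ref, pr$p)
    sum(log(pmax(full[cbind(seq_len(n), y)], 1e-300)))
  }

  theta <- matrix(0, K - 1L, 2L,
                  dimnames = list(lev[-1L], c("intercept", "slope")))
  ll <- loglik(theta)
  converged <- FALSE
  H <- NULL
  for (iter in seq_len(max_iter)) {
    pr <- probs(theta)$p                   # n x (K-1)
    G <- t(Y - pr) %*% X                   # (K-1) x 2 gradient blocks
    g <- as.vector(t(G))                   # order: k1(int,slope), k2(...)
    H <- matrix(0, P, P)
    for (a in seq_len(K - 1L)) {
      for (b in seq_len(K - 1L)) {
        w <- if (a == b) pr[, a] * (1 - pr[, a]) else -pr[, a] * pr[, b]
        blk <- crossprod(X, X * w)
        ia <- (a - 1L) * 2L + 1:2; ib <- (b - 1L) * 2L + 1:2
        H[ia, ib] <- blk
      }
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break               # singular information: separation
    stepm <- matrix(step, K - 1L, 2L, byrow = TRUE)
    lambda <- 1
    repeat {
      cand <- theta + lambda * stepm
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    theta <- theta + lambda * stepm
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  separation <- !converged && (is.null(H) || max(abs(theta)) > 30)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  se <- if (!is.null(vc)) matrix(sqrt(pmax(diag(vc), 0)), K - 1L, 2L,
                                 byrow = TRUE,
                                 dimnames = dimnames(theta)) else NULL
  structure(c(base, list(
    coefficients = theta, vcov = vc, se = se, logLik = ll,
    converged = converged, separation = separation)),
    class = "trajectory_model")
}

#' Predicted category frequencies at given times
#'
#' Softmax of the fitted linear predictors; rows sum to 1 to machine
#' precision. Categories fixed at 0 during fitting appear as zero columns.
#'
#' @param model a \code{\link{fit_multinomial}} result
#' @param times_bp numeric vector of times in years BP
#' @return matrix (length(times_bp) x categories) of frequencies
#' @export
predict_frequencies <- function(model, times_bp) {
  if (isTRUE(model$separation) && is.null(model$coefficients)) {
    stop("model is degenerate (complete separation); no frequencies")
  }
  s <- -times_bp / 1000
  theta <- model$coefficients
  eta <- cbind(0, cbind(1, s) %*% t(theta))
  m <- apply(eta, 1L, max)
  p <- exp(eta - m)
  p <- p / rowSums(p)
  colnames(p) <- model$categories
  if (length(model$dropped) > 0L) {
    zeros <- matrix(0, nrow(p), length(model$dropped),
                    dimnames = list(NULL, model$dropped))
    p <- cbind(p, zeros)
  }
  p
}

#' Fold change of summed category frequencies between two times
#'
#' Computes (sum of predicted frequencies of \code{category_set} at
#' \code{t1}) / (same at \code{t0}) with a delta-method confidence interval
#' on the log scale. A denominator below 1e-6 is reported as unbounded.
#'
#' @param model a \code{\link{fit_multinomial}} result
#' @param t0,t1 times in years BP (typically t0 old, t1 recent)
#' @param category_set categories to sum (default: the duplication-carrying
#'   classes)
#' @param level confidence level (default 0.95)
#' @return list(fold, lower, upper, f_t0, f_t1, unbounded)
#' @export
fold_change <- function(model, t0, t1,
                        category_set = grep("\\+$", model$categories,
                                            value = TRUE),
                        level = 0.95) {
  stopifnot(t0 != t1)
  fsum <- function(theta, t) {
    m2 <- model
    m2$coefficients <- theta
    p <- predict_frequencies(m2, t)
    sum(p[1, intersect(category_set, colnames(p))])
  }
  th <- model$coefficients
  f0 <- fsum(th, t0); f1 <- fsum(th, t1)
  if (f0 < 1e-6) {
    return(list(fold = Inf, lower = NA_real_, upper = NA_real_,
                f_t0 = f0, f_t1 = f1, unbounded = TRUE))
  }
  fold <- f1 / f0
  lo <- up <- NA_real_
  if (!is.null(model$vcov)) {
    # numeric gradient of log fold change wrt the packed coefficients
    eps <- 1e-6
    grad <- numeric(length(th))
    for (j in seq_along(th)) {
      thp <- th; thp[j] <- thp[j] + eps
      thm <- th; thm[j] <- thm[j] - eps
      grad[j] <- (log(fsum(thp, t1) / fsum(thp, t0)) -
                    log(fsum(thm, t1) / fsum(thm, t0))) / (2 * eps)
    }
    # vcov parameter order is k1(int,slope), k2(...): same as row-major theta
    gvec <- as.vector(t(th)); stopifnot(length(gvec) == length(grad))
    grad_packed <- as.vector(t(matrix(grad, nrow(th), 2L)))
    v <- drop(t(grad_packed) %*% model$vcov %*% grad_packed)
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- fold * exp(-z * sqrt(max(v, 0)))
    up <- fold * exp(z * sqrt(max(v, 0)))
  }
  list(fold = fold, lower = lo, upper = up, f_t0 = f0, f_t1 = f1,
       unbounded = FALSE)
}

#' Haplotype counts in half-open time bins
#'
#' Bins are [k*w, (k+1)*w) in years BP; an observation exactly on a boundary
#' belongs to the older bin that starts there. Counts are conserved.
#'
#' @param obs data.frame with columns \code{category} and \code{age_bp}
#' @param bin_width bin width in years
#' @return data.frame: bin_start, bin_end, one count column per category,
#'   and n (row total)
#' @export
bin_counts <- function(obs, bin_width) {
  stopifnot(bin_width > 0)
  k <- floor(obs$age_bp / bin_width)
  cats <- sort(unique(obs$category))
  bins <- sort(unique(k))
  tab <- table(factor(k, levels = bins),
               factor(obs$category, levels = cats))
  out <- data.frame(bin_start = bins * bin_width,
                    bin_end = (bins + 1) * bin_width)
  out <- cbind(out, as.data.frame.matrix(tab))
  out$n <- rowSums(tab)
  rownames(out) <- NULL
  out
}

#' Simulate aged haplotype observations from known logit parameters
#'
#' Draws observation ages uniformly on a time range and categories from the
#' multinomial-logit model — the ground-truth generator for
#' parameter-recovery checks of \code{\link{fit_multinomial}}.
#'
#' @param n number of haplotype observations
#' @param trajectory list(t_range, freq_present, freq_past); see
#'   \code{\link{default_trajectory}}
#' @param seed integer seed
#' @return data.frame with columns category, age_bp
#' @export
simulate_trajectory_obs <- function(n, trajectory = default_trajectory(),
                                    seed = 1L) {
  set.seed(seed)
  ages <- stats::runif(n, trajectory$t_range[1], trajectory$t_range[2])
  p <- trajectory_frequencies(trajectory, ages)
  cat <- vapply(seq_len(n), function(i)
    sample(colnames(p), 1L, prob = p[i, ]), "")
  data.frame(category = cat, age_bp = ages, stringsAsFactors = FALSE)
}
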