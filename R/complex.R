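#' Integrate inversion and copy-number calls into a diploid structural
#' genotype
#'
#' Given an individual's inversion genotype and integer alpha/beta copy
#' numbers, selects the haplotype pair from the expectation table whose
#' inversion genotype matches the call and whose expected copy numbers are
#' nearest (L1 distance on integer calls) to the observed ones. Exact
#' copy-number ties between pairs are broken by a rarity ranking: the pair
#' whose rarer member is more common wins, so a beta CN of 4 on an H1/H1
#' background resolves to beta2/beta2 rather than beta1/beta3, triple-copy
#' haplotypes being very rare. An observation matching no pair within L1
#' distance 1 is returned unresolved; copy number on the background where it
#' is impossible (alpha on H1/H1, beta on H2/H2) is flagged inconsistent.
#'
#' @param call one row of \code{\link{genotype_inversion}} output (or a list
#'   with \code{genotype})
#' @param alpha_cn,beta_cn integer diploid copy-number calls for the alpha
#'   and beta sectors (e.g. \code{cn_call} from \code{\link{sector_cn}})
#' @param table expectation table (default \code{\link{expectation_table}()})
#' @return one-row data.frame: hap1, hap2, resolved (logical), confidence
#'   ("high" when the observed CNs match exactly, "low" at L1 distance 1),
#'   l1_distance, note
#' @export
integrate_genotype <- function(call, alpha_cn, beta_cn,
                               table = expectation_table()) {
  unresolved <- function(note) data.frame(
    hap1 = NA_character_, hap2 = NA_character_, resolved = FALSE,
    confidence = "none", l1_distance = NA_real_, note = note,
    stringsAsFactors = FALSE)
  gt <- if (is.data.frame(call) || is.list(call)) call$genotype else call
  if (is.na(gt) || gt == "no-call") return(unresolved("no inversion call"))
  if (is.na(alpha_cn) || is.na(beta_cn)) {
    return(unresolved("missing copy-number call"))
  }
  cand <- table[table$inversion_genotype == gt, , drop = FALSE]
  l1 <- abs(cand$alpha_cn - alpha_cn) + abs(cand$beta_cn - beta_cn)
  best <- min(l1)
  if (best > 1) {
    # e.g. alpha CN > 2 with an H1/H1 call: CN on the impossible background
    note <- if ((gt == "H1/H1" && alpha_cn > 2) ||
                (gt == "H2/H2" && beta_cn > 2)) {
      "inconsistent: copy number conflicts with inversion call"
    } else {
      sprintf("no expectation within L1 distance 1 (best %d)", best)
    }
    return(unresolved(note))
  }
  cand <- cand[l1 == best, , drop = FALSE]
  if (nrow(cand) > 1L) {
    r1 <- rarity_rank(cand$hap1); r2 <- rarity_rank(cand$hap2)
    key <- order(pmax(r1, r2), r1 + r2)
    cand <- cand[key[1L], , drop = FALSE]
    note <- "tie broken by rarity ranking"
  } else {
    note <- ""
  }
  data.frame(hap1 = cand$hap1, hap2 = cand$hap2, resolved = TRUE,
             confidence = if (best == 0) "high" else "low",
             l1_distance = best, note = note, stringsAsFactors = FALSE)
}

#' Integrate a whole cohort
#'
#' Joins inversion calls with alpha/beta copy-number estimates by sample and
#' integrates each individual. Samples failing QC upstream are left
#' unresolved.
#'
#' @param calls \code{\link{genotype_inversion}} output
#' @param cn \code{\link{estimate_cohort_cn}} output
#' @param table expectation table
#' @return data.frame, one row per sample, with the integration columns plus
#'   the simplified category pair (\code{simple1}, \code{simple2})
#' @export
integrate_cohort <- function(calls, cn, table = expectation_table()) {
  get_cn <- function(id, sec) {
    row <- cn[cn$sample == id & cn$sector == sec, ]
    if (nrow(row) != 1L || row$qc != "pass") NA_integer_ else row$cn_call
  }
  out <- lapply(seq_len(nrow(calls)), function(i) {
    id <- calls$sample[i]
    g <- integrate_genotype(calls[i, ], get_cn(id, "alpha"),
                            get_cn(id, "beta"), table)
    cbind(sample = id, g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$simple1 <- ifelse(out$resolved, NA_character_, NA_character_)
  out$simple2 <- out$simple1
  ok <- out$resolved
  out$simple1[ok] <- simplify_haplotype(out$hap1[ok])
  out$simple2[ok] <- simplify_haplotype(out$hap2[ok])
  out
}

#' Simplify a diploid structural genotype
#'
#' Collapses both haplotypes of a resolved genotype to the four reportable
#' categories (unduplicated vs duplication-carrying, per orientation).
#'
#' @param genotype one-row data.frame from \code{\link{integrate_genotype}}
#' @return character vector of length 2 (sorted)
#' @export
simplify_genotype <- function(genotype) {
  if (!isTRUE(genotype$resolved)) stop("genotype is unresolved")
  sort(simplify_haplotype(c(genotype$hap1, genotype$hap2)))
}

#' Mendelian consistency of a trio of diploid structural genotypes
#'
#' A child is consistent with its parents iff its unordered haplotype pair
#' can be formed by taking one haplotype label from each parent.
#'
#' @param child,mother,father resolved genotypes
#'   (\code{\link{integrate_genotype}} rows, or length-2 character vectors
#'   of haplotype labels)
#' @return logical
#' @export
trio_check <- function(child, mother, father) {
  pair <- function(g) {
    if (is.character(g)) return(g)
    if (!isTRUE(g$resolved)) stop("unresolved genotype in trio")
    c(g$hap1, g$hap2)
  }
  ch <- pair(child); mo <- pair(mother); fa <- pair(father)
  (ch[1] %in% mo && ch[2] %in% fa) || (ch[2] %in% mo && ch[1] %in% fa)
}
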