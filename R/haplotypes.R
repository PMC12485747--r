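#' Structural haplotype labels
#'
#' A structural haplotype at an inversion + segmental-duplication locus is
#' described by its inversion orientation clade (H1 direct, H2 inverted) and
#' the copy count of the clade-specific KANSL1 duplicon: the beta duplicon
#' segregates exclusively on H1 backgrounds and the alpha duplicon exclusively
#' on H2 backgrounds. Labels follow the field's nomenclature:
#' \code{"H1.b1"} (equivalently \code{"H1.β1"}) is an unduplicated direct
#' haplotype, \code{"H2.a2"} an inverted haplotype carrying one extra alpha
#' copy. The numeric suffix counts duplicon copies (1 = unduplicated).
#'
#' @param label character vector of haplotype labels. Greek (α/β)
#'   and Latin (a/b) duplicon letters are both accepted.
#' @return \code{parse_haplotype}: a data.frame with columns
#'   \code{inversion} ("H1"/"H2"), \code{duplicon} ("alpha"/"beta"),
#'   \code{copies} (suffix integer), \code{plus} (TRUE for collapsed "2+"
#'   categories), \code{label} (canonical Greek-letter form).
#' @examples
#' parse_haplotype(c("H1.b2", "H2.a1"))
#' @export
parse_haplotype <- function(label) {
  lab <- as.character(label)
  m <- regmatches(lab, regexec("^(H1|H2)\\.([abαβ])([0-9]+)(\\+?)$", lab))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed haplotype label(s): ", paste(lab[bad], collapse = ", "))
  }
  inv <- vapply(m, `[`, "", 2L)
  dup_letter <- vapply(m, `[`, "", 3L)
  duplicon <- ifelse(dup_letter %in% c("a", "α"), "alpha", "beta")
  copies <- as.integer(vapply(m, `[`, "", 4L))
  plus <- vapply(m, `[`, "", 5L) == "+"
  ok <- (inv == "H1" & duplicon == "beta") | (inv == "H2" & duplicon == "alpha")
  if (any(!ok)) {
    stop("inconsistent label(s) (beta belongs on H1, alpha on H2): ",
         paste(lab[!ok], collapse = ", "))
  }
  if (any(copies < 1L)) stop("duplicon suffix must be >= 1")
  data.frame(
    inversion = inv, duplicon = duplicon, copies = copies, plus = plus,
    label = format_haplotype(inv, copies, plus),
    stringsAsFactors = FALSE
  )
}

#' @rdname parse_haplotype
#' @param inversion "H1" or "H2"
#' @param copies duplicon copy suffix (1 = unduplicated)
#' @param plus logical; TRUE marks a collapsed "2+" category
#' @export
format_haplotype <- function(inversion, copies, plus = FALSE) {
  letter <- ifelse(inversion == "H1", "β", "α")
  paste0(inversion, ".", letter, copies, ifelse(plus, "+", ""))
}

#' Collapse a haplotype label to its simplified reporting category
#'
#' Short-read pipelines report four categories: H1.β1, H1.β2+,
#' H2.α1 and H2.α2+ — haplotypes with any extra duplicon copy
#' collapse into the "+" class. The mapping is total and idempotent.
#'
#' @param label character vector of haplotype labels
#' @return character vector of simplified labels
#' @export
simplify_haplotype <- function(label) {
  p <- parse_haplotype(label)
  ifelse(p$copies >= 2L,
         format_haplotype(p$inversion, 2L, plus = TRUE),
         format_haplotype(p$inversion, 1L))
}

#' The four simplified haplotype categories
#' @return character vector of the four category labels in canonical order
#' @export
haplotype_categories <- function() {
  c(format_haplotype("H1", 1L), format_haplotype("H1", 2L, TRUE),
    format_haplotype("H2", 1L), format_haplotype("H2", 2L, TRUE))
}

#' Expected diploid copy numbers for a pair of structural haplotypes
#'
#' Every haplotype carries one copy of the alpha-unique and one copy of the
#' beta-unique sector in control-normalized units, so an unduplicated diploid
#' has alpha CN 2 and beta CN 2. Each extra duplicon copy adds 1 to the
#' corresponding sector: beta CN = 2 + extra beta copies (H1 side only),
#' alpha CN = 2 + extra alpha copies (H2 side only).
#'
#' @param hap1,hap2 haplotype labels
#' @return named numeric vector with elements \code{alpha} and \code{beta}
#' @export
expected_cn <- function(hap1, hap2) {
  p <- parse_haplotype(c(hap1, hap2))
  extra <- p$copies - 1L
  c(alpha = 2L + sum(extra[p$duplicon == "alpha"]),
    beta  = 2L + sum(extra[p$duplicon == "beta"]))
}

#' Build the diploid genotype expectation table
#'
#' Enumerates all unordered pairs of the configured haplotype labels and
#' tabulates, per pair, the inversion genotype implied by its H-clade counts
#' and the expected diploid alpha and beta copy numbers. The table is
#' explicit configuration so the integration rule is auditable; the default
#' label set covers suffixes 1..3 on both backgrounds.
#'
#' @param labels haplotype labels to enumerate (default suffixes 1..3 on both
#'   H1 and H2)
#' @return data.frame with columns hap1, hap2, inversion_genotype,
#'   alpha_cn, beta_cn
#' @export
expectation_table <- function(labels = default_haplotype_labels()) {
  p <- parse_haplotype(labels)
  n <- length(labels)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, "row"]; j <- idx[k, "col"]
    cn <- expected_cn(p$label[i], p$label[j])
    inv_gt <- paste(sort(c(p$inversion[i], p$inversion[j])), collapse = "/")
    data.frame(hap1 = p$label[i], hap2 = p$label[j],
               inversion_genotype = inv_gt,
               alpha_cn = cn[["alpha"]], beta_cn = cn[["beta"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname expectation_table
#' @export
default_haplotype_labels <- function() {
  c(format_haplotype("H1", 1:3), format_haplotype("H2", 1:3))
}

#' Rarity rank of a haplotype label (lower = more common)
#'
#' Population frequency decreases with duplicon copy number on both
#' backgrounds (beta1 > beta2 > beta3; alpha1 > alpha2 > alpha3), so the
#' rank is simply the copy suffix. Used to break ties between copy-number
#' interpretations: when two diploid assignments fit the observed copy
#' numbers equally well, the pair avoiding the rarer haplotype wins (e.g.
#' beta2/beta2 is preferred over beta1/beta3 because triple-beta haplotypes
#' are very rare).
#'
#' @param label haplotype labels
#' @return integer rarity ranks
#' @export
rarity_rank <- function(label) {
  parse_haplotype(label)$copies
}
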