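#' Inversion genotyping from tag-SNP genotype vectors
#'
#' Assigns each individual an inversion genotype by Euclidean distance
#' between its observed 0/1/2 tag-SNP vector and the three expected vectors:
#' all-0 (H1/H1), all-1 (H1/H2) and all-2 (H2/H2). Distances are computed
#' over the individual's non-missing sites only, with the expected vectors
#' restricted to the same sites, so no imputation is needed. The genotype is
#' the argmin of the three distances; an individual is a no-call when fewer
#' than \code{min_call_fraction} of panel sites are usable or when the two
#' best distances tie exactly.
#'
#' @param genotypes integer matrix (samples x panel SNPs), entries 0/1/2/NA
#'   with 2 meaning two H2-tagging alleles (see \code{\link{load_genotypes}})
#' @param min_call_fraction minimum fraction of non-missing panel sites for
#'   a call (default 0.5)
#' @return data.frame with one row per sample: \code{sample}, \code{genotype}
#'   (H1/H1, H1/H2, H2/H2 or no-call), the three distances \code{d_H1H1},
#'   \code{d_H1H2}, \code{d_H2H2}, their scale-free forms divided by
#'   sqrt(n_snps) (\code{*_norm}), \code{n_snps} used, \code{margin}
#'   (runner-up minus best distance) and a no-call \code{reason}
#' @examples
#' g <- rbind(s1 = c(0L, 1L, 2L))
#' genotype_inversion(g)  # distances sqrt(5), sqrt(2), sqrt(5) -> H1/H2
#' @export
genotype_inversion <- function(genotypes, min_call_fraction = 0.5) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 1L)
  labels <- c("H1/H1", "H1/H2", "H2/H2")
  res <- lapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    use <- !is.na(g)
    n_used <- sum(use)
    d <- vapply(0:2, function(e) sqrt(sum((g[use] - e)^2)), 0)
    row <- data.frame(
      sample = rownames(genotypes)[i] %||% as.character(i),
      genotype = "no-call",
      d_H1H1 = d[1], d_H1H2 = d[2], d_H2H2 = d[3],
      d_H1H1_norm = NA_real_, d_H1H2_norm = NA_real_, d_H2H2_norm = NA_real_,
      n_snps = n_used, margin = NA_real_, reason = "",
      stringsAsFactors = FALSE
    )
    if (n_used == 0L) {
      row$d_H1H1 <- row$d_H1H2 <- row$d_H2H2 <- NA_real_
      row$reason <- "no usable sites"
      return(row)
    }
    row[c("d_H1H1_norm", "d_H1H2_norm", "d_H2H2_norm")] <-
      as.list(d / sqrt(n_used))
    ord <- order(d)
    row$margin <- d[ord[2]] - d[ord[1]]
    if (n_used / ncol(genotypes) < min_call_fraction) {
      row$reason <- sprintf("call fraction %.2f below %.2f",
                            n_used / ncol(genotypes), min_call_fraction)
    } else if (row$margin == 0) {
      row$reason <- "distance tie"
    } else {
      row$genotype <- labels[ord[1]]
    }
    row
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write inversion calls as TSV
#' @param calls result of \code{\link{genotype_inversion}}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_inversion_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
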