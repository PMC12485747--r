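test_that("degenerate frequency distribution yields a uniform cohort", {
  cfg <- small_config(n = 50L,
                      haplotype_freqs = c("H1.β1" = 1.0))
  tr <- draw_cohort(cfg)
  expect_true(all(tr$individuals$hap1 == "H1.β1"))
  expect_true(all(tr$individuals$hap2 == "H1.β1"))
})

test_that("haplotype frequencies converge within binomial error", {
  cfg <- small_config(n = 2000L, seed = 1L,
                      haplotype_freqs = c("H1.β1" = 0.5, "H2.α2" = 0.5))
  tr <- draw_cohort(cfg)
  frac <- mean(c(tr$individuals$hap1, tr$individuals$hap2) == "H2.α2")
  sd3 <- 3 * sqrt(0.5 * 0.5 / 4000)
  expect_lt(abs(frac - 0.5), sd3)
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(haplotype_freqs = c("H1.β1" = 0.6,
                                                "H2.α1" = 0.3)),
               "sum to 1")
  expect_error(small_config(mean_coverage = 0), "positive")
  expect_error(
    small_config(recomb_tracts = list(list(individual = 1L, start = 0L,
                                           end = 50L, donor = "H1"))),
    "outside")
})

test_that("simulation is byte-identical under a fixed seed", {
  run <- function() {
    cfg <- small_config(n = 20L, seed = 42L)
    tr <- draw_cohort(cfg)
    tg <- simulate_tag_genotypes(tr, cfg)
    sn <- simulate_inversion_snps(tr, cfg)
    dp <- simulate_depth(tr, small_sectors(), cfg)
    vcf <- tempfile(fileext = ".vcf")
    write_vcf(sn$genotypes, sn$positions, sn$contig, vcf)
    list(tr = tr, tg = tg, sn = sn, dp = dp,
         vcf_bytes = readBin(vcf, "raw", file.size(vcf)))
  }
  a <- run()
  b <- run()
  expect_identical(a$tr$individuals, b$tr$individuals)
  expect_identical(a$tg$genotypes, b$tg$genotypes)
  expect_identical(a$sn$genotypes, b$sn$genotypes)
  expect_identical(a$dp$depth, b$dp$depth)
  expect_identical(a$vcf_bytes, b$vcf_bytes)
})

test_that("tag genotypes equal the H2 count when error-free", {
  cfg <- small_config(n = 30L, tag_error_rate = 0, seed = 3L)
  tr <- draw_cohort(cfg)
  tg <- simulate_tag_genotypes(tr, cfg)
  h2 <- (parse_haplotype(tr$individuals$hap1)$inversion == "H2") +
    (parse_haplotype(tr$individuals$hap2)$inversion == "H2")
  expect_true(all(tg$genotypes == matrix(h2, nrow = 30L,
                                         ncol = cfg$n_tag_snps)))
})

test_that("tag errors occur at the configured binomial rate", {
  cfg <- small_config(n = 1L, seed = 9L, tag_error_rate = 0.01,
                      n_tag_snps = 1000L,
                      haplotype_freqs = c("H1.β1" = 1.0))
  tr <- draw_cohort(cfg)
  tg <- simulate_tag_genotypes(tr, cfg)
  # H1/H1 individual: every non-zero entry is a flipped allele
  n_flipped <- sum(tg$genotypes)
  mu <- 2000 * 0.01
  expect_lt(abs(n_flipped - mu), 3 * sqrt(2000 * 0.01 * 0.99))
})

test_that("normalized control depth is calibrated at 1", {
  cfg <- small_config(n = 25L, seed = 5L, mean_coverage = 20)
  tr <- draw_cohort(cfg)
  dp <- simulate_depth(tr, small_sectors(), cfg)
  cn <- estimate_cohort_cn(dp, small_sectors())
  # every true-CN-2 alpha sector should estimate ~2, i.e. control ~1
  base <- cn[cn$sector == "alpha", ]
  m <- merge(base, tr$individuals, by.x = "sample", by.y = "sample_id")
  ratio <- m$cn_continuous / m$alpha_cn
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("sector depth scales with true copy number", {
  cfg <- small_config(n = 40L, seed = 6L,
                      haplotype_freqs = c("H1.β2" = 1.0))
  tr <- draw_cohort(cfg)  # every beta CN = 4, i.e. 2x the control level
  dp <- simulate_depth(tr, small_sectors(), cfg)
  cn <- estimate_cohort_cn(dp, small_sectors())
  beta <- cn[cn$sector == "beta", ]
  expect_lt(max(abs(beta$cn_continuous / 2 - 2.0)), 0.1)
})

test_that("summed NSF depth recovers total copies", {
  cfg <- small_config(n = 10L, seed = 7L, nsf_extra_copies = 2L)
  tr <- draw_cohort(cfg)  # 6 total NSF copies
  dp <- simulate_depth(tr, small_sectors(), cfg)
  cn <- estimate_cohort_cn(dp, small_sectors())
  nsf <- cn[cn$sector == "nsf", ]
  expect_true(all(abs(nsf$cn_continuous - 6) < 0.3))
  expect_true(all(nsf$cn_call == 6L))
})

test_that("trajectory-stamped cohorts match the logit model per time bin", {
  cfg <- small_config(n = 1500L, seed = 8L, trajectory = default_trajectory())
  tr <- draw_cohort(cfg)
  obs <- cohort_haplotype_obs(tr)
  expect_equal(nrow(obs), 2L * 1500L)
  bins <- bin_counts(obs, 3000)
  for (r in seq_len(nrow(bins))) {
    mid <- (bins$bin_start[r] + bins$bin_end[r]) / 2
    p_true <- trajectory_frequencies(default_trajectory(), mid)[1, ]
    for (cat in names(p_true)) {
      obs_frac <- bins[[cat]][r] / bins$n[r]
      tol <- 3 * sqrt(p_true[[cat]] * (1 - p_true[[cat]]) / bins$n[r]) + 0.02
      expect_lt(abs(obs_frac - p_true[[cat]]), tol)
    }
  }
})

test_that("recombination tracts are implanted on exactly one haplotype", {
  cfg0 <- small_config(n = 50L, seed = 10L)
  tr0 <- draw_cohort(cfg0)
  het <- which(true_inversion_genotype(tr0) == "H1/H2")[1]
  tract <- list(list(individual = het, start = 150000L, end = 250000L,
                     donor = "H1"))
  cfg <- small_config(n = 50L, seed = 10L, recomb_tracts = tract,
                      haplotype_divergence = 1.0)
  tr <- draw_cohort(cfg)
  sn <- simulate_inversion_snps(tr, cfg)
  in_tract <- sn$positions >= 150000 & sn$positions < 250000
  # at divergence 1 an H1/H2 het is all-1 outside the tract; inside, the H2
  # haplotype copies the H1 pool, so the individual matches H1/H1 genotypes
  h1_hom <- which(true_inversion_genotype(tr) == "H1/H1")[1]
  expect_true(all(sn$genotypes[het, in_tract] ==
                    sn$genotypes[h1_hom, in_tract]))
  expect_true(all(sn$genotypes[het, !in_tract] == 1L))
})
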