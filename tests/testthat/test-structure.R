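make_blocks <- function(...) {
  ids <- c(...)
  data.frame(block_id = ids, orientation = "+",
             length = seq_along(ids) * 10000, stringsAsFactors = FALSE)
}

test_that("singleton blocks are removed", {
  blocks <- lapply(1:10, function(i) make_blocks("A", "B", "C"))
  names(blocks) <- paste0("h", 1:10)
  blocks$h1 <- rbind(blocks$h1,
                     data.frame(block_id = "PRIV", orientation = "+",
                                length = 99000))
  d <- make_decomp(blocks)
  f <- filter_bundles(d, min_length_quantile = 0)
  expect_false("PRIV" %in% f$block_id)
  expect_true(all(c("A", "B", "C") %in% f$block_id))
})

test_that("the length-quantile filter drops the shortest quartile", {
  blocks <- lapply(1:4, function(i) {
    data.frame(block_id = c("A", "B", "C", "D"), orientation = "+",
               length = c(10, 20, 30, 40) * 1000)
  })
  names(blocks) <- paste0("h", 1:4)
  d <- make_decomp(blocks)
  f <- filter_bundles(d)  # quantile 0.25 of {10,20,30,40} kb = 17.5 kb
  expect_false("A" %in% f$block_id)
  expect_true(all(c("B", "C", "D") %in% f$block_id))
  expect_equal(unname(attr(f, "min_length")), 17500)
})

test_that("filtering is idempotent", {
  with_seed(11, {
    for (rep in 1:10) {
      n_h <- sample(3:8, 1)
      pool <- paste0("B", 1:8)
      blocks <- lapply(seq_len(n_h), function(i) {
        ids <- sample(pool, sample(3:6, 1), replace = TRUE)
        data.frame(block_id = ids,
                   orientation = sample(c("+", "-"), length(ids), TRUE),
                   length = sample(5:50, length(ids)) * 1000)
      })
      names(blocks) <- paste0("h", seq_len(n_h))
      d <- make_decomp(blocks)
      f1 <- tryCatch(filter_bundles(d), error = function(e) NULL)
      if (is.null(f1)) next
      f2 <- filter_bundles(f1)
      strip <- function(x) {
        attributes(x)[c("min_length", "empty_haplotypes")] <- NULL
        rownames(x) <- NULL
        x
      }
      expect_identical(strip(f2), strip(f1))
      expect_equal(attr(f2, "min_length"), attr(f1, "min_length"))
    }
  })
})

test_that("structure signatures canonicalize strand flips", {
  s1 <- structure_signature(c("A", "B", "C"), c("+", "-", "+"))
  s2 <- structure_signature(c("C", "B", "A"), c("-", "+", "-"))
  expect_identical(s1, s2)
  # an extra block copy is a different structure
  s3 <- structure_signature(c("A", "B", "B", "C"), c("+", "-", "-", "+"))
  expect_false(identical(s1, s3))
})

test_that("grouping collects identical and strand-flipped haplotypes", {
  d <- make_decomp(list(
    h1 = data.frame(block_id = c("A", "B", "C"),
                    orientation = c("+", "-", "+"),
                    length = c(30, 40, 50) * 1000),
    h2 = data.frame(block_id = c("A", "B", "C"),
                    orientation = c("+", "-", "+"),
                    length = c(30, 40, 50) * 1000),
    h3 = data.frame(block_id = c("C", "B", "A"),
                    orientation = c("-", "+", "-"),
                    length = c(50, 40, 30) * 1000),
    h4 = data.frame(block_id = c("A", "C"), orientation = c("+", "+"),
                    length = c(30, 50) * 1000)))
  g <- group_structures(d)
  expect_equal(nrow(g$groups), 2L)
  expect_setequal(g$groups$n_haplotypes, c(3L, 1L))
  expect_identical(g$assignment[["h1"]], g$assignment[["h3"]])
})

test_that("weighted jaccard distances match hand computations", {
  d <- make_decomp(list(
    h1 = data.frame(block_id = c("A", "B", "C"), orientation = "+",
                    length = c(10, 20, 30) * 1000),
    h2 = data.frame(block_id = c("A", "B", "D"), orientation = "+",
                    length = c(10, 20, 40) * 1000),
    h3 = data.frame(block_id = c("A", "B", "C"), orientation = "+",
                    length = c(10, 20, 30) * 1000),
    h4 = data.frame(block_id = c("E", "F"), orientation = "+",
                    length = c(15, 25) * 1000)))
  j <- jaccard_matrix(d)
  s_abc <- structure_signature(c("A", "B", "C"), rep("+", 3))
  s_abd <- structure_signature(c("A", "B", "D"), rep("+", 3))
  s_ef <- structure_signature(c("E", "F"), rep("+", 2))
  expect_equal(j$dist[s_abc, s_abc], 0)
  # shared A+B = 30 kb of a 100 kb union -> distance 0.7
  expect_equal(j$dist[s_abc, s_abd], 0.7)
  expect_equal(j$dist[s_abc, s_ef], 1)
  expect_equal(unname(j$multiplicity[s_abc]), 2L)
})

test_that("jaccard distances are symmetric and satisfy the triangle inequality", {
  with_seed(12, {
    for (rep in 1:10) {
      pool <- paste0("B", 1:6)
      blocks <- lapply(1:5, function(i) {
        ids <- sample(pool, sample(2:5, 1), replace = TRUE)
        data.frame(block_id = ids, orientation = "+",
                   length = sample(10:40, length(ids)) * 1000)
      })
      names(blocks) <- paste0("h", 1:5)
      j <- jaccard_matrix(make_decomp(blocks))
      D <- j$dist
      expect_equal(D, t(D))
      expect_true(all(diag(D) == 0))
      n <- nrow(D)
      for (a in 1:n) for (b in 1:n) for (c in 1:n) {
        expect_lte(D[a, b], D[a, c] + D[c, b] + 1e-12)
      }
    }
  })
})

test_that("summary grouping merges near-identical structures", {
  d <- make_decomp(list(
    h1 = data.frame(block_id = c("A", "B", "C"), orientation = "+",
                    length = c(100, 100, 5) * 1000),
    h2 = data.frame(block_id = c("A", "B"), orientation = "+",
                    length = c(100, 100) * 1000),
    h3 = data.frame(block_id = c("D", "E"), orientation = "+",
                    length = c(80, 90) * 1000)))
  j <- jaccard_matrix(d)
  grp <- summary_structures(j, h = 0.1)
  s1 <- group_structures(d)$assignment[["h1"]]
  s2 <- group_structures(d)$assignment[["h2"]]
  s3 <- group_structures(d)$assignment[["h3"]]
  expect_equal(grp[[s1]], grp[[s2]])   # 5/205 jaccard apart: merged
  expect_false(grp[[s1]] == grp[[s3]])
})
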