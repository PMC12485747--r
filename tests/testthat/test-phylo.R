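random_binary_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::rtree(n, tip.label = paste0("t", seq_len(n)))
}

test_that("neighbor joining recovers additive trees exactly", {
  with_seed(21, {
    for (n in 4:8) {
      for (rep in 1:5) {
        true <- random_binary_tree(n)
        true$edge.length <- runif(nrow(true$edge), 0.5, 3)
        D <- ape::cophenetic.phylo(true)
        labs <- paste0("t", seq_len(n))
        D <- D[labs, labs]
        est <- nj_tree(D)
        expect_equal(rf_distance(est, true), 0)
        # path distances reproduce the input matrix on additive inputs
        D_est <- ape::cophenetic.phylo(est)[labs, labs]
        expect_equal(D_est, D, tolerance = 1e-8)
        # agrees with an independent NJ implementation topologically
        expect_equal(rf_distance(est, ape::nj(D)), 0)
      }
    }
  })
})

test_that("three taxa resolve by the closed-form three-point formulas", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("ties break deterministically and negative branches clamp to zero", {
  # equidistant 4 taxa: every join equally good; lowest index pair joins
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(paste0("t", 1:4), paste0("t", 1:4))
  a <- nj_tree(D)
  b <- nj_tree(D)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_true(all(a$edge.length >= 0))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("Robinson-Foulds distance matches hand and brute-force values", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1,E:1);")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 4)
  expect_error(rf_distance(t1, ape::rtree(5)), "leaf set")
  with_seed(22, {
    for (rep in 1:40) {
      n <- sample(4:7, 1)
      a <- random_binary_tree(n)
      b <- random_binary_tree(n)
      expect_equal(rf_distance(a, b), brute_force_rf(a, b))
    }
  })
})

test_that("RF is a metric attaining 2(n-3) on disjoint-split pairs", {
  with_seed(23, {
    seen_max <- FALSE
    for (rep in 1:30) {
      n <- sample(5:7, 1)
      a <- random_binary_tree(n)
      b <- random_binary_tree(n)
      c <- random_binary_tree(n)
      dab <- rf_distance(a, b)
      expect_equal(dab, rf_distance(b, a))
      expect_lte(dab, 2 * (n - 3))
      expect_lte(dab, rf_distance(a, c) + rf_distance(c, b))
      if (dab == 2 * (n - 3)) seen_max <- TRUE
    }
    expect_true(seen_max)
  })
})

test_that("RF distance handles polytomies", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  poly <- ape::read.tree(text = "(A,B,C,D,E);")  # star: no nontrivial splits
  expect_equal(rf_distance(t1, poly), 2)
})

test_that("LD window selection returns the anchor plus its nearest trees", {
  rf <- matrix(c(0, 4, 6, 2,
                 4, 0, 5, 6,
                 6, 5, 0, 2,
                 2, 6, 2, 0), 4, 4, byrow = TRUE)
  # anchor row (2, 6, 2, 0): windows 1 and 3 tie at distance 2 and the
  # genomically nearer window 3 wins the tie
  expect_equal(select_ld_windows(rf, k = 1), c(3, 4))
  expect_equal(select_ld_windows(rf, k = 2), c(1, 3, 4))
  expect_equal(sort(select_ld_windows(rf, k = 3)), 1:4)
  expect_warning(sel <- select_ld_windows(rf, k = 4), "all windows")
  expect_equal(sel, 1:4)
})

test_that("windowed RF analysis selects the low-distance windows on simulation", {
  # nine windows: the last three share one topology, the rest are random
  with_seed(24, {
    shared <- random_binary_tree(12)
    trees <- c(lapply(1:6, function(i) random_binary_tree(12)),
               lapply(1:3, function(i) shared))
    rf <- rf_matrix(trees)
    expect_equal(dim(rf), c(9L, 9L))
    sel <- select_ld_windows(rf, k = 2)
    expect_equal(sel, c(7L, 8L, 9L))
    # MDS embeds the zero-distance cluster at a single point
    xy <- rf_mds(rf)
    expect_lt(max(dist(xy[7:9, ])), 1e-8)
  })
})

test_that("node-age calibration scales depths linearly", {
  # clock tree: root at depth 4, calibration clade at depth 2
  tr <- ape::read.tree(text = "((A:2,B:2):2,(C:2,D:2):2);")
  cal <- calibrate_node_ages(tr, c("A", "B"), age = 18.13)
  ages <- cal$ages
  root_id <- as.character(length(tr$tip.label) + 1L)
  expect_equal(unname(ages[root_id]), 36.26)
  expect_equal(unname(ages[as.character(cal$calibration_node)]), 18.13)
  # doubling every branch length leaves the ages unchanged
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  cal2 <- calibrate_node_ages(tr2, c("A", "B"), age = 18.13)
  expect_equal(cal2$ages, cal$ages)
})

test_that("calibration round-trips generated clock trees", {
  with_seed(25, {
    for (rep in 1:10) {
      tr <- ape::rcoal(10)
      true_ages <- ape::branching.times(tr)
      clade <- ape::extract.clade(tr, as.integer(names(true_ages)[2]))
      cal <- calibrate_node_ages(tr, clade$tip.label,
                                 age = true_ages[2] * 7.74)
      got <- cal$ages[names(true_ages)]
      expect_equal(unname(got), unname(true_ages * 7.74), tolerance = 1e-9)
    }
  })
})

test_that("calibration validates its inputs", {
  tr <- ape::read.tree(text = "((A:2,B:2):2,(C:2,D:2):2);")
  expect_error(calibrate_node_ages(ape::unroot(tr), c("A", "B"), 5),
               "rooted")
  expect_error(calibrate_node_ages(tr, c("A", "Z"), 5), "absent")
  ragged <- ape::read.tree(text = "((A:9,B:1):2,(C:2,D:2):2);")
  expect_warning(calibrate_node_ages(ragged, c("C", "D"), 5), "clock")
})
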