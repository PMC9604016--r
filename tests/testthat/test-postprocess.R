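test_that("quotient normalization matches hand-computed values", {
  # 2x2 fixture, all four cells worked out by hand:
  # ML = (-8, -6), MT = (-8, -6)
  # V(1,1) = -10/((-8-8)/2) = 1.25      V(1,2) = -6/((-8-6)/2) = 6/7
  # V(2,1) = -6/((-6-8)/2) = 6/7        V(2,2) = -6/((-6-6)/2) = 1
  s <- matrix(c(-10, -6, -6, -6), 2, 2, byrow = TRUE,
              dimnames = list(c("L1", "L2"), c("T1", "T2")))
  nm <- normalize_method1(score_matrix(s))
  expect_equal(nm$values, matrix(c(1.25, 6/7, 6/7, 1), 2, 2, byrow = TRUE,
                                 dimnames = dimnames(s)), tolerance = 1e-12)

  # constant matrix: symmetry forces V0 = ML = MT, so V = 1 and sigma = 0
  cm <- matrix(-8, 3, 4, dimnames = list(paste0("L", 1:3), paste0("T", 1:4)))
  ncm <- normalize_method1(score_matrix(cm))
  expect_true(all(ncm$values == 1))
  expect_equal(ncm$matrix_sd, 0)

  # scale invariance: the quotient is unchanged under V0 -> 3 * V0
  s3 <- random_score_matrix(5, 4, seed = 21)
  expect_equal(normalize_method1(score_matrix(3 * s3))$values,
               normalize_method1(score_matrix(s3))$values, tolerance = 1e-12)
})

test_that("three-sigma selection is inclusive and handles degenerate sigma", {
  # plant one strong cell; only it should exceed M + 3*sigma
  s <- random_score_matrix(10, 10, seed = 4)
  s[3, 7] <- s[3, 7] - 12
  p <- threshold_method1(normalize_method1(score_matrix(s)))
  expect_equal(nrow(p), 1L)
  expect_equal(p$target_id, "T07")
  expect_equal(p$ligand_id, "L03")

  # constant matrix: every defined cell equals M, all pass inclusively
  cm <- matrix(-8, 3, 3, dimnames = list(paste0("L", 1:3), paste0("T", 1:3)))
  expect_message(pc <- threshold_method1(normalize_method1(score_matrix(cm))),
                 "degenerate")
  expect_equal(nrow(pc), 9L)
})

test_that("two-directional Z-transformation matches a cell-by-cell oracle", {
  # includes a constant row, exercising the zero-SD policy (Z = 0)
  s <- matrix(c(-12, -7, -7,
                -8, -8, -8,
                -6, -9, -9), 3, 3, byrow = TRUE,
              dimnames = list(paste0("L", 1:3), paste0("T", 1:3)))
  z <- ztransform_2d(score_matrix(s))
  o <- oracle_zcomb(s)
  expect_equal(z$ZT, o$ZT, tolerance = 1e-12)
  expect_equal(z$ZL, o$ZL, tolerance = 1e-12)
  expect_equal(z$Zcomb, o$Zcomb, tolerance = 1e-12)
  # hand values: row 1 standardizes to (-sqrt(2), 1/sqrt(2), 1/sqrt(2))
  expect_equal(unname(z$ZT[1, ]), c(-sqrt(2), 1/sqrt(2), 1/sqrt(2)),
               tolerance = 1e-12)
  expect_true(all(z$ZT[2, ] == 0))
})

test_that("Z matrices standardize their axis: mean 0, SD 1", {
  for (seed in 1:5) {
    s <- random_score_matrix(8, 6, seed = seed)
    z <- ztransform_2d(score_matrix(s))
    expect_true(all(abs(rowMeans(z$ZT)) < 1e-9))
    expect_true(all(abs(colMeans(z$ZL)) < 1e-9))
    expect_true(all(abs(apply(z$ZT, 1, function(x)
      sqrt(mean((x - mean(x))^2))) - 1) < 1e-9))
    expect_true(all(abs(apply(z$ZL, 2, function(x)
      sqrt(mean((x - mean(x))^2))) - 1) < 1e-9))
  }
})

test_that("orientation swap exchanges the two Z matrices", {
  s <- random_score_matrix(6, 5, seed = 13)
  a <- ztransform_2d(score_matrix(s))
  b <- ztransform_2d(score_matrix(s), orientation = "swapped")
  expect_equal(a$ZT, b$ZL)
  expect_equal(a$ZL, b$ZT)
})

test_that("per-ligand best-target selection honors its contracts", {
  # a -5 SD planted cell must be selected for its ligand
  s <- random_score_matrix(10, 8, seed = 5)
  s[4, 2] <- s[4, 2] - 5 * 1.5
  p <- select_best_targets(ztransform_2d(score_matrix(s)))
  expect_equal(p$target_id[p$ligand_id == "L04"], "T02")
  # one pairing per ligand when all rows are defined
  expect_equal(nrow(p), 10L)
  expect_equal(sort(p$ligand_id), sort(rownames(s)))

  # exact two-way tie: duplicated target columns -> lexicographically
  # smaller id wins
  s2 <- random_score_matrix(5, 3, seed = 6)
  s2 <- cbind(s2, s2[, 2, drop = FALSE])
  colnames(s2) <- c("T01", "TB", "T03", "TA")  # TB and TA identical columns
  s2[, c("TB", "TA")] <- matrix(rep(apply(s2[, c("T01", "T03")], 1, min) - 2,
                                    2), ncol = 2)
  p2 <- select_best_targets(ztransform_2d(score_matrix(s2)))
  expect_true(all(p2$target_id == "TA"))
})

test_that("ligands with no defined Zcomb are omitted", {
  s <- random_score_matrix(6, 4, seed = 8)
  s[2, ] <- NA_real_
  expect_warning(z <- ztransform_2d(score_matrix(s)), "<2 defined")
  p <- select_best_targets(z)
  expect_false("L02" %in% p$ligand_id)
  expect_equal(nrow(p), 5L)
})

test_that("both methods agree with brute-force oracles on small matrices", {
  cases <- expand.grid(nr = 3:5, nc = 3:5)
  for (k in seq_len(nrow(cases))) {
    s <- random_score_matrix(cases$nr[k], cases$nc[k], seed = 100 + k,
                             missing = if (k %% 3 == 0) 1 else 0)
    m <- validate_scores(score_matrix(s))
    o1 <- oracle_method1(m$scores)
    n1 <- normalize_method1(m)
    expect_equal(n1$values, o1$V, tolerance = 1e-9)
    expect_equal(n1$matrix_mean, o1$M, tolerance = 1e-9)
    expect_equal(n1$matrix_sd, o1$sigma, tolerance = 1e-9)
    expect_equal(pair_keys(threshold_method1(n1)), o1$pairs)
    oz <- oracle_zcomb(m$scores)
    z <- ztransform_2d(m)
    expect_equal(z$Zcomb, oz$Zcomb, tolerance = 1e-9)
  }
})

test_that("method I selection is invariant under positive scaling", {
  s <- random_score_matrix(30, 10, seed = 31)
  s[5, 5] <- s[5, 5] - 8
  base <- pair_keys(run_method(validate_scores(score_matrix(s)), "method1"))
  for (c in c(0.5, 3, 10)) {
    scaled <- pair_keys(run_method(validate_scores(score_matrix(c * s)),
                                   "method1"))
    expect_equal(scaled, base)
  }
})

test_that("method II selection is invariant under global affine transforms", {
  s <- random_score_matrix(20, 8, seed = 32)
  base <- pair_keys(select_best_targets(ztransform_2d(score_matrix(s))))
  for (ab in list(c(2, -1), c(0.5, -3), c(3, -10))) {
    t <- ab[1] * s + ab[2]
    got <- pair_keys(select_best_targets(ztransform_2d(score_matrix(t))))
    expect_equal(got, base)
  }
})

test_that("run_method dispatches and labels pairing sets", {
  s <- random_score_matrix(12, 6, seed = 41)
  m <- validate_scores(score_matrix(s))
  p2 <- run_method(m, "method2", run = "excl_promiscuous")
  expect_lte(nrow(p2), 12L)
  expect_true(all(p2$method == "method2"))
  expect_true(all(p2$run == "excl_promiscuous"))
  expect_true(all(p2$program == "docking"))
})
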