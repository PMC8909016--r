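test_that("all three base algorithms separate two far blobs", {
  b <- make_blobs(n_per = 10, d = 5, sep = 8, seed = 3)
  for (alg in c("HC", "SOM", "PC")) {
    labels <- base_cluster(b$X, alg, k = 2, seed = 7)
    expect_equal(mclust::adjustedRandIndex(labels, b$truth), 1,
                 info = alg)
  }
})

test_that("cluster counts outside 2..9 are rejected", {
  b <- make_blobs(n_per = 5, d = 3)
  expect_error(base_cluster(b$X, "HC", k = 1), "between 2 and 9")
  expect_error(base_cluster(b$X, "HC", k = 10), "between 2 and 9")
  expect_error(base_cluster(b$X[1:3, ], "HC", k = 5), "exceeds")
})

test_that("hierarchical clustering of n = k distinct points is singletons", {
  X <- matrix(c(0, 10, 20, 35), 4, 1)
  labels <- base_cluster(X, "HC", k = 4)
  expect_equal(sort(unique(labels)), 1:4)
})

test_that("one full-fraction replicate gives the 0/1 co-membership matrix", {
  b <- make_blobs(n_per = 6, d = 4, sep = 8, seed = 2)
  cm <- consensus_matrix(b$X, "HC", k = 2, n_reps = 1, fraction = 1, seed = 1)
  labels <- base_cluster(b$X, "HC", k = 2, seed = 1)
  expect_equal(cm$values, outer(labels, labels, `==`) * 1,
               ignore_attr = TRUE)
})

test_that("consensus matrices are symmetric, bounded and reproducible", {
  set.seed(8)
  X <- matrix(rnorm(30 * 4), 30, 4)
  cm1 <- consensus_matrix(X, "HC", k = 3, n_reps = 25, seed = 5)
  cm2 <- consensus_matrix(X, "HC", k = 3, n_reps = 25, seed = 5)
  expect_identical(cm1$values, cm2$values)
  expect_true(isSymmetric(cm1$values))
  expect_true(all(cm1$values >= 0 & cm1$values <= 1))
  expect_true(all(diag(cm1$values) == 1))
  cm3 <- consensus_matrix(X, "HC", k = 3, n_reps = 25, seed = 6)
  expect_false(identical(cm1$values, cm3$values))
})

test_that("planted two-blob structure yields a near-binary consensus", {
  b <- make_blobs(n_per = 12, d = 6, sep = 8, seed = 4)
  cm <- consensus_matrix(b$X, "HC", k = 2, n_reps = 40, seed = 9)
  within <- outer(b$truth, b$truth, `==`)
  expect_gt(min(cm$values[within]), 0.99)
  expect_lt(max(cm$values[!within]), 0.01)
})

test_that("CDF-area rule selects the planted cluster count", {
  # Construct per-k consensus matrices directly: perfect 2-block structure
  # at k = 2; k >= 3 splits a block ambiguously (entries 0.5).
  n <- 10
  truth <- rep(1:2, each = 5)
  perfect <- outer(truth, truth, `==`) * 1
  ambiguous <- perfect
  ambiguous[1:5, 1:5] <- 0.5
  diag(ambiguous) <- 1
  ms <- list(`2` = perfect, `3` = ambiguous, `4` = ambiguous)
  sel <- select_k(ms)
  expect_equal(sel$k, 2)
  expect_equal(unname(sel$areas[1]), 25 / 45)  # between-pair fraction

  # flat consensus: deltas are flat and the tie resolves to the smallest k
  flat <- matrix(0.4, n, n); diag(flat) <- 1
  sel_flat <- select_k(list(`2` = flat, `3` = flat, `4` = flat))
  expect_equal(sel_flat$k, 2)

  expect_error(select_k(list(`2` = perfect, `4` = perfect)), "consecutive")

  # BIC route: the selection follows the best (largest, mclust sign) BIC
  sel_bic <- select_k(ms, bic = c(`2` = -100, `3` = -90, `4` = -120))
  expect_equal(sel_bic$k, 3)
})

test_that("label alignment maximizes agreement over cluster permutations", {
  ref <- c(rep(1, 10), rep(2, 10))
  swapped <- ifelse(ref == 1, 2, 1)
  expect_equal(align_labels(ref, swapped), ref)

  # confusion [[10,0],[0,10]] -> identity, agreement 20
  expect_equal(align_labels(ref, ref), ref)

  # confusion [[2,8],[9,1]]: other cluster 1 = 2 ref-1 + 8 ref-2, etc.
  ref2 <- c(rep(1, 11), rep(2, 9))
  other <- c(rep(1, 2), rep(2, 9), rep(1, 8), rep(2, 1))
  aligned <- align_labels(ref2, other)
  expect_equal(sum(aligned == ref2), 17)  # enumeration over both 2-perms

  # alignment never reduces agreement (random 4-cluster cases)
  set.seed(10)
  for (i in 1:20) {
    a <- sample(1:4, 40, replace = TRUE)
    b2 <- sample(1:4, 40, replace = TRUE)
    expect_gte(sum(align_labels(a, b2) == a), sum(b2 == a))
  }

  expect_error(align_labels(1:4, 1:5), "same samples")
})

test_that("alignment agrees with exhaustive permutation search on toys", {
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  set.seed(14)
  for (i in 1:20) {
    ref <- sample(1:3, 15, replace = TRUE)
    other <- sample(1:3, 15, replace = TRUE)
    best <- max(vapply(perms3, function(p) sum(p[other] == ref), 0))
    expect_equal(sum(align_labels(ref, other) == ref), best)
  }
})

test_that("meta-consensus keeps exactly the samples all algorithms agree on", {
  l1 <- c(1, 1, 2, 2, 1)
  meta_all <- meta_consensus(list(l1, l1, l1))
  expect_equal(meta_all$assigned, 1:5)
  expect_equal(length(meta_all$unassigned), 0)

  l2 <- l1; l2[3] <- 1  # one algorithm differs on sample 3 only
  meta <- meta_consensus(list(l1, l1, l2))
  expect_equal(meta$unassigned, 3)
  expect_equal(meta$labels[-3], l1[-3])
  expect_true(is.na(meta$labels[3]))

  # three-way agreement is contained in every pairwise agreement set
  set.seed(6)
  ls <- replicate(3, sample(1:2, 30, replace = TRUE), simplify = FALSE)
  meta3 <- meta_consensus(ls)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    pairwise <- which(ls[[pair[1]]] == ls[[pair[2]]])
    expect_true(all(meta3$assigned %in% pairwise))
  }

  expect_error(meta_consensus(list(l1, l1)), "three labelings")
})

test_that("agreement fraction never grows as more algorithms must concur", {
  set.seed(61)
  ls <- replicate(4, sample(1:2, 50, replace = TRUE), simplify = FALSE)
  frac3 <- length(meta_consensus(ls[1:3])$assigned)
  frac4 <- length(meta_consensus(ls)$assigned)
  expect_lte(frac4, frac3)
})

test_that("naive-Bayes extension labels held-out structure correctly", {
  b <- make_blobs(n_per = 30, d = 8, sep = 2, seed = 19)
  labels <- b$truth
  held <- c(1:10, 31:40)
  lab_na <- labels; lab_na[held] <- NA
  meta <- structure(
    list(labels = lab_na, assigned = setdiff(1:60, held), unassigned = held),
    class = "meta_consensus"
  )
  full <- extend_with_naive_bayes(b$X, meta)
  expect_equal(full$labels[meta$assigned], labels[meta$assigned])
  expect_equal(full$source[meta$assigned], rep("meta", 40))
  expect_equal(full$source[held], rep("nb", 20))
  expect_gte(mean(full$labels[held] == labels[held]), 0.95)

  # an unassigned duplicate of an assigned sample takes that sample's class
  X2 <- rbind(b$X, b$X[15, ])
  meta2 <- structure(
    list(labels = c(labels[1:60], NA), assigned = 1:60, unassigned = 61L),
    class = "meta_consensus"
  )
  full2 <- extend_with_naive_bayes(X2, meta2)
  expect_equal(full2$labels[61], labels[15])

  # empty unassigned set: a strict no-op
  meta3 <- structure(
    list(labels = labels, assigned = 1:60, unassigned = integer(0)),
    class = "meta_consensus"
  )
  full3 <- extend_with_naive_bayes(b$X, meta3)
  expect_identical(full3$labels, labels)

  # a class with < 2 assigned samples has no variance estimate
  meta4 <- structure(
    list(labels = c(1, rep(2, 59)), assigned = 1:60,
         unassigned = integer(0)),
    class = "meta_consensus"
  )
  expect_error(extend_with_naive_bayes(b$X, meta4), "fewer than 2")
})

test_that("gaussian naive Bayes matches an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(23)
  X <- matrix(rnorm(80 * 5), 80, 5)
  X[41:80, ] <- X[41:80, ] + 1.5
  labels <- rep(1:2, each = 40)
  train <- c(1:30, 41:70)
  test <- setdiff(1:80, train)
  meta <- structure(
    list(labels = replace(labels, test, NA), assigned = train,
         unassigned = test),
    class = "meta_consensus"
  )
  ours <- extend_with_naive_bayes(X, meta)
  ref <- e1071::naiveBayes(data.frame(X[train, ]), factor(labels[train]))
  theirs <- as.integer(as.character(
    predict(ref, data.frame(X[test, , drop = FALSE]))
  ))
  expect_gt(mean(ours$labels[test] == theirs), 0.95)
})
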