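make_sep_data <- function(n = 20, margin = 4, seed = 2) {
  set.seed(seed)
  labels <- rep(c(FALSE, TRUE), each = n / 2)
  X <- rbind(
    SEPGENE = ifelse(labels, margin, -margin) + rnorm(n, 0, 0.1),
    NOISE1 = rnorm(n),
    NOISE2 = rnorm(n)
  )
  colnames(X) <- sprintf("S%02d", seq_len(n))
  list(X = X, labels = labels)
}

test_that("a perfectly separating gene dominates the fit", {
  d <- make_sep_data()
  m <- myc_train(d$X, d$labels, penalty = 1e-4)
  expect_equal(names(which.max(abs(m$weights))), "SEPGENE")
  expect_equal(myc_loocv(d$X, d$labels, penalty = 1e-4), 1.0)
})

test_that("extreme shrinkage collapses to the prevalence intercept", {
  d <- make_sep_data()
  m <- myc_train(d$X, d$labels, penalty = 1e6)
  expect_true(all(m$weights == 0))
  sc <- myc_score(m, d$X)
  expect_equal(unique(round(sc$score, 10)), round(mean(d$labels), 10))
})

test_that("scores follow the inverse-logit closed form and the tie rule", {
  m <- structure(
    list(weights = c(G1 = 0), intercept = 0, alpha = 0.1, penalty = 0.1,
         cutoff = 0.5, center = c(G1 = 0), scale = c(G1 = 1), genes = "G1"),
    class = "myc_model"
  )
  X <- matrix(c(0, 1), 1, 2, dimnames = list("G1", c("a", "b")))
  sc <- myc_score(m, X)
  expect_equal(sc$score, c(0.5, 0.5))
  expect_equal(sc$class, c("Low", "Low"))  # exact cutoff is Low

  m$weights <- c(G1 = 1)
  X2 <- matrix(c(0, log(3)), 1, 2, dimnames = list("G1", c("a", "b")))
  sc2 <- myc_score(m, X2)
  expect_equal(sc2$score, c(0.5, 0.75))
  expect_equal(sc2$class, c("Low", "High"))

  expect_error(
    myc_score(m, matrix(0, 1, 1, dimnames = list("OTHER", "a"))),
    "G1"
  )
})

test_that("scores are invariant to gene ordering of the input matrix", {
  d <- make_sep_data()
  m <- myc_train(d$X, d$labels)
  shuffled <- d$X[c(3, 1, 2), ]
  expect_equal(myc_score(m, d$X)$score, myc_score(m, shuffled)$score)
})

test_that("training rejects degenerate inputs", {
  d <- make_sep_data()
  expect_error(myc_train(d$X, rep(TRUE, 20)), "both classes")
  expect_error(myc_train(d$X[, 1:3], d$labels[1:3]), "4 training samples")
  bad <- d$X; bad[1, 1] <- NA
  expect_error(myc_train(bad, d$labels), "missing")
})

test_that("gene importance is the normalized absolute weight", {
  m <- structure(
    list(weights = c(B = 2, A = -1, C = 1), intercept = 0, alpha = 0.1,
         penalty = 0.1, cutoff = 0.5, center = numeric(3), scale = rep(1, 3),
         genes = c("B", "A", "C")),
    class = "myc_model"
  )
  imp <- gene_importance(m)
  expect_equal(imp$importance, c(50, 25, 25))
  expect_equal(imp$gene, c("B", "A", "C"))  # name breaks the 25/25 tie
  expect_equal(sum(imp$importance), 100)

  m$weights <- c(B = 0, A = 0, C = 3)
  expect_equal(gene_importance(m)$importance[1], 100)

  m$weights <- c(B = 0, A = 0, C = 0)
  expect_warning(imp0 <- gene_importance(m), "zero")
  expect_true(all(imp0$importance == 0))
})

test_that("LOOCV on pure noise stays near chance", {
  set.seed(33)
  X <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:30)))
  labels <- rep(c(FALSE, TRUE), 15)
  acc <- myc_loocv(X, labels)
  half <- stats::qnorm(0.995) * sqrt(0.25 / 30)
  expect_lt(abs(acc - 0.5), half)
})

test_that("LOOCV handles a fold whose training labels degenerate", {
  set.seed(5)
  X <- matrix(rnorm(6), 2, 3, dimnames = list(c("G1", "G2"), NULL))
  labels <- c(TRUE, FALSE, FALSE)  # leaving out sample 1 leaves one class
  expect_no_error(acc <- myc_loocv(X, labels))
  expect_true(acc >= 0 && acc <= 1)
  expect_error(myc_loocv(X[, 1:2], labels[1:2]), "3 samples")
})

test_that("the fitted score recovers the planted training-cohort labels", {
  co <- generate_cohort(cohort_config(n_samples = 0, seed = 12))
  tr <- normalize_counts(co$training$counts, co$panel)
  genes <- panel_genes(co$panel, "myc_panel")
  m <- myc_train(tr, co$training$labels, genes = genes)
  sc <- myc_score(m, tr)
  # the score separates planted classes essentially perfectly
  expect_gt(rank_auc(sc$score, co$training$labels), 0.99)
  # and rises with the staining percentage the labels were derived from
  expect_gt(spearman(sc$score, co$training$ihc_percent), 0.7)
  # MYC itself is the planted driver and must rank first
  expect_equal(gene_importance(m)$gene[1], "MYC")
})

test_that("IHC concordance reproduces hand-computed confusion metrics", {
  # TP = 9, FN = 1, FP = 3, TN = 7
  classes <- rep(c("High", "Low", "High", "Low"), c(9, 1, 3, 7))
  ihc <- rep(c(80, 90, 20, 10), c(9, 1, 3, 7))
  scores <- seq(0, 1, length.out = 20)
  cc <- ihc_concordance(scores, classes, ihc)
  expect_equal(cc$sensitivity, 0.9)
  expect_equal(cc$specificity, 0.7)
  expect_equal(cc$ppv, 0.75)
  expect_equal(cc$npv, 0.875)

  perfect <- ihc_concordance(c(0.9, 0.8, 0.1), c("High", "High", "Low"),
                             c(70, 60, 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  mono <- ihc_concordance(c(0.1, 0.4, 0.9), c("Low", "Low", "High"),
                          c(10, 50, 90))
  expect_equal(mono$spearman_rho, 1)

  expect_error(ihc_concordance(1, "High", NA_real_), "no evaluable")
})
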