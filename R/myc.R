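#' @name myc_activity
#' @title Elastic-net MYC activity classifier
#'
#' @description
#' A logistic elastic-net classifier of MYC transcriptional activity,
#' trained on a small IHC-anchored training cohort over a 34-gene panel and
#' applied to new samples as a probability-like score in \[0, 1\].
#' Hyperparameters follow the published setup: mixing `alpha = 0.1`,
#' regularization strength `penalty = 0.1`, classification cutoff 0.5
#' (score strictly greater than the cutoff is called High). Features are
#' standardized on the training data and the training statistics are
#' reused at scoring time.
NULL

# Restrict a normalized matrix to the model's genes, samples x genes,
# erroring on any gene that is absent.
myc_feature_matrix <- function(X, genes) {
  values <- if (inherits(X, "normalized_matrix")) X$values else X
  missing <- setdiff(genes, rownames(values))
  if (length(missing) > 0) {
    stop("expression matrix is missing model gene(s): ",
         paste(missing, collapse = ", "))
  }
  t(values[genes, , drop = FALSE])
}

#' Train the MYC activity model
#'
#' @param X a `normalized_matrix` (or genes x samples matrix of log2
#'   values) containing the MYC-panel genes.
#' @param labels logical (or coercible) per-sample MYC-high indicator.
#' @param genes the panel genes to use; default all rows of `X` (pass
#'   `panel_genes(panel, "myc_panel")` to restrict).
#' @param alpha elastic-net mixing parameter in \[0,1\] (default 0.1).
#' @param penalty regularization strength lambda (default 0.1).
#' @param cutoff score threshold for the High call (default 0.5).
#' @return A list of class `myc_model`: per-gene `weights`, `intercept`,
#'   the hyperparameters, and the training standardization (`center`,
#'   `scale`).
#' @export
myc_train <- function(X, labels, genes = NULL, alpha = 0.1, penalty = 0.1,
                      cutoff = 0.5) {
  values <- if (inherits(X, "normalized_matrix")) X$values else X
  genes <- genes %||% rownames(values)
  feats <- myc_feature_matrix(X, genes)
  labels <- as.logical(labels)
  if (nrow(feats) != length(labels)) stop("labels must match samples")
  if (anyNA(feats) || anyNA(labels)) stop("missing values are not allowed")
  if (nrow(feats) < 4) stop("at least 4 training samples are required")
  if (length(unique(labels)) < 2) {
    stop("training labels must contain both classes")
  }
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0,1)")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]")

  fit_enet(feats, labels, genes, alpha, penalty, cutoff)
}

# Standardize-and-fit core shared by myc_train() and the LOOCV folds
# (which may legitimately be smaller than the user-facing minimum).
fit_enet <- function(feats, labels, genes, alpha, penalty, cutoff) {
  center <- colMeans(feats)
  scale <- apply(feats, 2, stats::sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(feats, 2, center, `-`), 2, scale, `/`)
  fit <- glmnet::glmnet(Z, factor(labels, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = alpha,
                        lambda = penalty, standardize = FALSE)
  w <- as.numeric(fit$beta)
  names(w) <- genes
  structure(
    list(weights = w, intercept = as.numeric(fit$a0), alpha = alpha,
         penalty = penalty, cutoff = cutoff, center = center, scale = scale,
         genes = genes),
    class = "myc_model"
  )
}

#' Score samples with a fitted MYC model
#'
#' @param model a `myc_model`.
#' @param X a `normalized_matrix` or genes x samples matrix containing all
#'   model genes.
#' @return `data.frame(sample_id, score, class)` where `score` is the
#'   inverse-logit of the linear predictor on the training standardization
#'   and `class` is `"High"` iff `score > cutoff` (ties are Low).
#' @export
myc_score <- function(model, X) {
  stopifnot(inherits(model, "myc_model"))
  feats <- myc_feature_matrix(X, model$genes)
  Z <- sweep(sweep(feats, 2, model$center, `-`), 2, model$scale, `/`)
  eta <- model$intercept + as.numeric(Z %*% model$weights)
  score <- stats::plogis(eta)
  data.frame(
    sample_id = rownames(feats) %||% seq_along(score),
    score = score,
    class = ifelse(score > model$cutoff, "High", "Low"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Leave-one-out cross-validated accuracy
#'
#' Refits the elastic net on each n-1 subset and classifies the held-out
#' sample at the cutoff. A fold whose training subset degenerates to a
#' single class predicts that class (the penalized intercept-only limit).
#'
#' @inheritParams myc_train
#' @return Fraction of held-out samples classified correctly.
#' @export
myc_loocv <- function(X, labels, genes = NULL, alpha = 0.1, penalty = 0.1,
                      cutoff = 0.5) {
  values <- if (inherits(X, "normalized_matrix")) X$values else X
  genes <- genes %||% rownames(values)
  labels <- as.logical(labels)
  n <- length(labels)
  if (n < 3) stop("LOOCV requires at least 3 samples")
  feats <- myc_feature_matrix(X, genes)
  correct <- vapply(seq_len(n), function(i) {
    tr_labels <- labels[-i]
    if (length(unique(tr_labels)) < 2) {
      # degenerate fold: the penalized fit collapses to the only class seen
      pred <- tr_labels[1]
    } else {
      pred <- tryCatch({
        m <- fit_enet(feats[-i, , drop = FALSE], tr_labels, genes,
                      alpha, penalty, cutoff)
        myc_score(m, t(feats[i, , drop = FALSE]))$class == "High"
      }, error = function(e) {
        # folds too small for the solver fall back to the intercept-only
        # limit: majority class, ties resolved to Low like the score rule
        mean(tr_labels) > 0.5
      })
    }
    pred == labels[i]
  }, NA)
  mean(correct)
}

#' Per-gene importance of a fitted model
#'
#' For a single linear layer, combining absolute connection weights reduces
#' to the normalized absolute coefficients: `|w_g| / sum(|w|) * 100`.
#'
#' @param model a `myc_model`.
#' @return `data.frame(gene, importance)` sorted by decreasing importance
#'   (gene name breaks ties). All-zero weights give all-zero importances
#'   with a warning.
#' @export
gene_importance <- function(model) {
  stopifnot(inherits(model, "myc_model"))
  w <- abs(model$weights)
  total <- sum(w)
  if (total == 0) {
    warning("all model weights are zero; importances undefined (reported 0)")
    imp <- w
  } else {
    imp <- w / total * 100
  }
  out <- data.frame(gene = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$gene), , drop = FALSE]
}

#' Concordance of the MYC score with MYC IHC staining
#'
#' Dichotomizes IHC at >= 50% positive tumor cells and compares it with
#' the model's High/Low call; also reports the Spearman correlation of the
#' continuous score with the staining percentage. Samples with missing IHC
#' are excluded pairwise.
#'
#' @param scores numeric per-sample MYC scores.
#' @param classes per-sample `"High"`/`"Low"` calls.
#' @param ihc_percent per-sample staining percentages in \[0,100\] (NA
#'   allowed).
#' @param ihc_cutoff IHC positivity threshold (default 50).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `spearman_rho` and the underlying 2x2 `table`.
#' @export
ihc_concordance <- function(scores, classes, ihc_percent, ihc_cutoff = 50) {
  ok <- !is.na(ihc_percent) & !is.na(classes)
  if (!any(ok)) stop("no evaluable sample pairs (all IHC values missing)")
  if (any(ihc_percent[ok] < 0 | ihc_percent[ok] > 100)) {
    stop("ihc_percent must lie in [0,100]")
  }
  pred <- classes[ok] == "High"
  truth <- ihc_percent[ok] >= ihc_cutoff
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  rho <- if (length(unique(scores[ok])) < 2 ||
             length(unique(ihc_percent[ok])) < 2) {
    NA_real_
  } else {
    stats::cor(scores[ok], ihc_percent[ok], method = "spearman")
  }
  list(
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn), spearman_rho = rho,
    table = matrix(c(tp, fn, fp, tn), 2, 2,
                   dimnames = list(pred = c("High", "Low"),
                                   ihc = c("positive", "negative")))
  )
}
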