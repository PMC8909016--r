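#' @name consensus_clustering
#' @title Resampling consensus clustering with three base algorithms
#'
#' @description
#' Monti-style consensus clustering: each of three base algorithms —
#' agglomerative hierarchical clustering (HC, Euclidean distance, average
#' linkage), a one-dimensional self-organizing map (SOM, k x 1 node grid,
#' winning node = cluster), and a Gaussian finite mixture model fit by EM
#' (PC, probabilistic clustering) — is run on 200 random 80% subsamples for
#' each candidate cluster count k in 2..9. The consensus matrix entry for a
#' sample pair is the fraction of co-subsampled replicates in which the pair
#' co-clustered. k is selected by the relative change in area under the
#' consensus CDF (HC, SOM) or by BIC (PC). Per-algorithm labelings are
#' aligned by optimal cluster-ID assignment; samples on which all three
#' algorithms agree form the meta-consensus, and the remainder are assigned
#' by a Gaussian naive-Bayes classifier trained on the meta-consensus
#' samples.
NULL

check_k <- function(k, n) {
  if (!is.numeric(k) || length(k) != 1L || k != floor(k) || k < 2 || k > 9) {
    stop("k must be an integer between 2 and 9")
  }
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
}

# k x 1-grid batch self-organizing map. Nodes live on a line; updates pull
# each node toward samples weighted by a Gaussian neighborhood on the grid
# whose radius shrinks over iterations. Winning node = cluster label.
som_cluster <- function(X, k, seed, n_iter = 30) {
  n <- nrow(X)
  proto <- with_seed(seed, X[sample.int(n, k), , drop = FALSE])
  grid <- seq_len(k)
  radii <- seq(from = max(k / 2, 0.5), to = 0.1, length.out = n_iter)
  bmu <- rep(1L, n)
  for (it in seq_len(n_iter)) {
    d2 <- outer(rowSums(X^2), rowSums(proto^2), `+`) - 2 * X %*% t(proto)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-outer(grid[bmu], grid, `-`)^2 / (2 * radii[it]^2))
    proto <- (t(h) %*% X) / colSums(h)
  }
  d2 <- outer(rowSums(X^2), rowSums(proto^2), `+`) - 2 * X %*% t(proto)
  max.col(-d2, ties.method = "first")
}

# Gaussian mixture clustering via mclust, trying diagonal covariance models
# from least to more flexible; returns labels with the model BIC attached.
pc_cluster <- function(X, k, seed) {
  fit <- NULL
  for (mn in c("EEI", "EII", "VII")) {
    fit <- with_seed(seed, tryCatch(
      mclust::Mclust(X, G = k, modelNames = mn, verbose = FALSE),
      error = function(e) NULL
    ))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # Degenerate geometry (e.g. exactly duplicated points): fall back to a
    # seeded k-means partition so the replicate still contributes.
    km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 5))
    labels <- km$cluster
    attr(labels, "bic") <- NA_real_
    return(labels)
  }
  labels <- as.integer(fit$classification)
  attr(labels, "bic") <- as.numeric(fit$bic)
  labels
}

#' Cluster samples with one base algorithm
#'
#' @param X samples x features numeric matrix (typically per-gene z-scaled
#'   log2 expression, transposed; see [zscale_genes()]).
#' @param algorithm `"HC"`, `"SOM"` or `"PC"`.
#' @param k number of clusters, an integer in 2..9.
#' @param seed integer seed (HC is deterministic; SOM/PC draw their
#'   initialization from it).
#' @return Integer cluster labels of length `nrow(X)`; for `"PC"` the model
#'   BIC is attached as attribute `"bic"`.
#' @export
base_cluster <- function(X, algorithm = c("HC", "SOM", "PC"), k, seed = 1L) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  check_k(k, nrow(X))
  switch(algorithm,
    HC = {
      hc <- stats::hclust(stats::dist(X), method = "average")
      unname(stats::cutree(hc, k = k))
    },
    SOM = as.integer(som_cluster(X, k, seed)),
    PC = pc_cluster(X, k, seed)
  )
}

#' Build a consensus matrix by resampling
#'
#' For each replicate, draws `ceiling(fraction * n)` samples without
#' replacement, clusters them, and tallies co-clustering; the consensus
#' entry for a pair is its co-cluster count divided by its co-sample count.
#' Pairs never co-sampled (essentially impossible at the default 200 x 80%)
#' get 0 with a warning.
#'
#' @inheritParams base_cluster
#' @param n_reps number of resampling replicates (default 200).
#' @param fraction subsampling fraction (default 0.8).
#' @return A list of class `consensus_matrix`: `values` (n x n, symmetric,
#'   in \[0,1\], diagonal 1 for co-sampled samples), `k`, `algorithm`,
#'   `n_reps`, `fraction`.
#' @export
consensus_matrix <- function(X, algorithm, k, n_reps = 200, fraction = 0.8,
                             seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  check_k(k, n)
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0,1]")
  m <- ceiling(fraction * n)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (r in seq_len(n_reps)) {
    rs <- child_seed(seed, r)
    idx <- with_seed(rs, sort(sample.int(n, m)))
    labels <- base_cluster(X[idx, , drop = FALSE], algorithm, k,
                           seed = child_seed(rs, 1))
    ind <- outer(labels, labels, `==`)
    co_cluster[idx, idx] <- co_cluster[idx, idx] + ind
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
  }
  values <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  seen <- co_sample > 0
  values[seen] <- co_cluster[seen] / co_sample[seen]
  if (!all(seen)) {
    warning("some sample pairs were never co-sampled; their consensus is 0")
  }
  structure(
    list(values = values, k = k, algorithm = algorithm, n_reps = n_reps,
         fraction = fraction),
    class = "consensus_matrix"
  )
}

# Area under the empirical CDF of the off-diagonal consensus entries over
# [0,1]. For the right-continuous empirical CDF this integral equals
# 1 - mean(entries).
consensus_cdf_area <- function(cm) {
  v <- if (inherits(cm, "consensus_matrix")) cm$values else cm
  off <- v[upper.tri(v)]
  1 - mean(off)
}

#' Select the number of clusters from per-k consensus matrices
#'
#' Computes the area A(k) under the consensus CDF for each k and the
#' relative change Delta(k): `Delta(k_min) = A(k_min)` and
#' `Delta(k) = (A(k) - A(k-1)) / A(k-1)` for larger k. The chosen k is
#' `argmax Delta(k)` (first maximum, so flat profiles resolve to the
#' smallest k). If per-k BIC values are supplied (the probabilistic
#' clustering route), `k_bic = argmin BIC` is reported as well and becomes
#' the selection.
#'
#' @param matrices named list of `consensus_matrix` objects for consecutive
#'   k (names are the k values, e.g. `"2"`..`"9"`).
#' @param bic optional named numeric vector of BIC values per k (mclust
#'   convention: larger is better; the selection takes the maximum).
#' @return List with `k` (the selection), `areas`, `deltas`, and (when
#'   `bic` given) `bic` and `k_bic`.
#' @export
select_k <- function(matrices, bic = NULL) {
  ks <- as.integer(names(matrices))
  if (any(is.na(ks)) || length(ks) == 0) {
    stop("matrices must be a named list with k values as names")
  }
  if (!identical(ks, seq(min(ks), max(ks)))) {
    stop("k values must be consecutive (got ", paste(ks, collapse = ","), ")")
  }
  areas <- vapply(matrices, consensus_cdf_area, 0)
  names(areas) <- ks
  deltas <- c(areas[1], diff(areas) / utils::head(areas, -1))
  names(deltas) <- ks
  chosen <- ks[which.max(deltas)]
  out <- list(k = chosen, areas = areas, deltas = deltas)
  if (!is.null(bic)) {
    out$bic <- bic
    out$k_bic <- as.integer(names(bic)[which.max(bic)])
    out$k <- out$k_bic
  }
  out
}

# All permutations of 1..k as a list (k <= 7 is used).
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Align one labeling's cluster IDs to a reference
#'
#' Finds the cluster-ID permutation of `other` maximizing agreement with
#' `reference` (exhaustively for up to 7 clusters, greedily above) and
#' returns the relabeled vector. Agreement never decreases.
#'
#' @param reference,other integer label vectors over the same samples.
#' @return `other` with permuted cluster IDs.
#' @export
align_labels <- function(reference, other) {
  if (length(reference) != length(other)) {
    stop("labelings must cover the same samples")
  }
  k <- max(reference, other)
  conf <- table(factor(other, levels = seq_len(k)),
                factor(reference, levels = seq_len(k)))
  if (k <= 7) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p) {
      sum(conf[cbind(seq_len(k), p)])
    }, 0)
    best <- perms[[which.max(scores)]]
  } else {
    # Greedy: repeatedly take the largest remaining confusion cell.
    best <- integer(k)
    cf <- as.matrix(conf)
    for (i in seq_len(k)) {
      cell <- which(cf == max(cf), arr.ind = TRUE)[1, ]
      best[cell[1]] <- cell[2]
      cf[cell[1], ] <- -1
      cf[, cell[2]] <- -1
    }
  }
  best[other]
}

#' Meta-consensus of three aligned labelings
#'
#' @param labelings list of at least three aligned integer label vectors
#'   over the same samples (three in the standard pipeline).
#' @return A list of class `meta_consensus`: `labels` (the common label
#'   where all three agree, `NA` otherwise), `assigned` / `unassigned`
#'   (index vectors, disjoint, covering all samples).
#' @export
meta_consensus <- function(labelings) {
  if (!is.list(labelings) || length(labelings) < 3) {
    stop("meta-consensus requires three labelings")
  }
  lens <- lengths(labelings)
  if (length(unique(lens)) != 1) stop("labelings must cover the same samples")
  agree <- Reduce(`&`, lapply(labelings[-1],
                              function(l) l == labelings[[1]]))
  labels <- ifelse(agree, labelings[[1]], NA_integer_)
  structure(
    list(labels = labels, assigned = which(agree), unassigned = which(!agree)),
    class = "meta_consensus"
  )
}

# Gaussian naive Bayes with a variance floor; priors are training class
# frequencies.
nb_train <- function(X, labels) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("naive Bayes requires at least 2 classes")
  small <- classes[vapply(classes, function(cl) sum(labels == cl), 0L) < 2]
  if (length(small) > 0) {
    stop("class(es) with fewer than 2 training samples: ",
         paste(small, collapse = ", "))
  }
  floor_var <- 1e-3 * mean(apply(X, 2, stats::var))
  if (!is.finite(floor_var) || floor_var <= 0) floor_var <- 1e-8
  stats_by_class <- lapply(classes, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    list(mean = colMeans(Xi),
         var = pmax(apply(Xi, 2, stats::var), floor_var),
         prior = nrow(Xi) / nrow(X))
  })
  names(stats_by_class) <- classes
  structure(list(classes = classes, stats = stats_by_class),
            class = "nb_model")
}

nb_predict <- function(model, X) {
  logpost <- vapply(model$classes, function(cl) {
    st <- model$stats[[as.character(cl)]]
    ll <- -0.5 * colSums((t(X) - st$mean)^2 / st$var) -
      0.5 * sum(log(2 * pi * st$var))
    ll + log(st$prior)
  }, numeric(nrow(X)))
  logpost <- matrix(logpost, nrow = nrow(X))
  model$classes[max.col(logpost, ties.method = "first")]
}

#' Extend a meta-consensus labeling to all samples with naive Bayes
#'
#' Fits a Gaussian naive-Bayes classifier (per-class per-feature mean and
#' floored variance, priors = training class frequencies) on the
#' meta-consensus samples and predicts the cluster of each unassigned
#' sample by maximum posterior. Meta-consensus labels are never changed.
#'
#' @param X samples x features matrix (same rows as the labelings).
#' @param meta a [meta_consensus()] result.
#' @param training optional list with `X` and `labels` to train the
#'   classifier on external data instead of the meta-consensus samples.
#' @return A list: `labels` (full integer labeling), `source` (`"meta"` or
#'   `"nb"` per sample), `nb_model`.
#' @export
extend_with_naive_bayes <- function(X, meta, training = NULL) {
  stopifnot(inherits(meta, "meta_consensus"))
  X <- as.matrix(X)
  if (length(meta$labels) != nrow(X)) stop("X must match the labelings")
  if (length(meta$assigned) == 0) stop("meta-consensus assigned no samples")
  if (is.null(training)) {
    training <- list(X = X[meta$assigned, , drop = FALSE],
                     labels = meta$labels[meta$assigned])
  }
  model <- nb_train(as.matrix(training$X), training$labels)
  labels <- meta$labels
  source <- ifelse(is.na(labels), "nb", "meta")
  if (length(meta$unassigned) > 0) {
    labels[meta$unassigned] <-
      nb_predict(model, X[meta$unassigned, , drop = FALSE])
  }
  list(labels = labels, source = source, nb_model = model)
}
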