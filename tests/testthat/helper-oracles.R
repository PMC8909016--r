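# Independent oracles used to check package computations.

# Two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration
# over all tables with the observed margins (probability-mass criterion).
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Efron-tie Cox partial log-likelihood for a single covariate, written
# directly from the definition (event-time by event-time).
cox_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    sum_r <- sum(exp(beta * x[r_idx]))
    sum_d <- sum(exp(beta * x[d_idx]))
    ll <- ll + beta * sum(x[d_idx])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

# Grid maximizer of the hand-written partial likelihood.
cox_brute_force <- function(time, event, x, grid = seq(-5, 5, by = 0.0005)) {
  ll <- vapply(grid, cox_efron_loglik, 0, time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Rank-based AUC of a score against a binary truth (Mann-Whitney form).
rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Normalization fixture: 5 endogenous genes x 3 samples (the block whose
# values are checked against a hand-computed spreadsheet), plus the 6
# housekeeping genes and control probes the normalization contract
# requires. Numbers are chosen so every step is easy hand arithmetic.
make_norm_toy <- function() {
  panel <- panel_definition(
    gene_id = c(paste0("G", 1:5), paste0("HK", 1:6), "P1", "P2", "N1", "N2"),
    role = c(rep("endogenous", 5), rep("housekeeping", 6),
             rep("pos_control", 2), rep("neg_control", 2)),
    signature = rep("none", 15)
  )
  counts <- rbind(
    G1 = c(10, 40, 20),
    G2 = c(3, 8, 6),
    G3 = c(100, 220, 130),
    G4 = c(0, 2, 4),
    G5 = c(50, 90, 60),
    HK1 = c(100, 210, 90),
    HK2 = c(100, 190, 110),
    HK3 = c(100, 200, 100),
    HK4 = c(100, 200, 100),
    HK5 = c(100, 200, 100),
    HK6 = c(100, 200, 100),
    P1 = c(60, 120, 90),
    P2 = c(40, 80, 60),
    N1 = c(2, 4, 6),
    N2 = c(2, 4, 2)
  )
  colnames(counts) <- c("A", "B", "C")
  list(panel = panel, counts = counts)
}

# A tiny cohort configuration used for fast pipeline-level tests.
small_config <- function(n = 60, seed = 11, ...) {
  pipeline_config(
    cohort = cohort_config(n_samples = n, seed = seed),
    consensus = list(n_reps = 40, fraction = 0.8, k_range = 2:4),
    seed = seed, ...
  )
}

# Two well-separated Gaussian blobs (samples x features).
make_blobs <- function(n_per = 20, d = 10, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per * d), n_per, d),
    matrix(stats::rnorm(n_per * d, mean = sep), n_per, d)
  )
  rownames(X) <- sprintf("B%02d", seq_len(2 * n_per))
  list(X = X, truth = rep(1:2, each = n_per))
}
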