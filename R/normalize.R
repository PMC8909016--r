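#' @name normalization
#' @title Control-probe and housekeeping normalization of panel counts
#'
#' @description
#' Count normalization for targeted nCounter-style panels, composed of
#' three per-sample corrections applied in order, then a log transform:
#'
#' 1. **technical factor** — positive-control probe sums estimate technical
#'    assay variation; each sample is scaled so its positive-control sum
#'    equals the cohort mean;
#' 2. **background level** — the mean of the negative-control probes is
#'    subtracted from every endogenous/housekeeping count, floored at 0;
#' 3. **content factor** — sums of the six housekeeping genes estimate RNA
#'    sample content; each sample is scaled to the cohort-mean housekeeping
#'    sum;
#' 4. `log2(x + pseudocount)`.
#'
#' Control probes are dropped from the output; housekeeping genes are kept
#' (display z-scaling downstream may use them).
NULL

count_submatrix <- function(counts, panel, roles) {
  counts[panel$role %in% roles, , drop = FALSE]
}

#' Technical (positive-control) scaling factors
#'
#' @param counts genes x samples count matrix (rows match `panel`).
#' @param panel the [panel_definition()] describing the rows.
#' @return Per-sample factor: mean positive-control sum across samples
#'   divided by the sample's positive-control sum. Multiplying each sample
#'   by its factor equalizes positive-control sums.
#' @rdname normalization
#' @export
technical_factor <- function(counts, panel) {
  pos <- count_submatrix(counts, panel, "pos_control")
  if (nrow(pos) == 0) stop("no positive-control probes in panel")
  sums <- colSums(pos)
  if (any(sums == 0)) {
    stop("positive-control sum is zero for sample(s): ",
         paste(colnames(counts)[sums == 0], collapse = ", "))
  }
  mean(sums) / sums
}

#' Background (negative-control) levels
#'
#' @return Per-sample background: the mean negative-control count.
#' @rdname normalization
#' @export
background_level <- function(counts, panel) {
  neg <- count_submatrix(counts, panel, "neg_control")
  if (nrow(neg) == 0) stop("no negative-control probes in panel")
  colMeans(neg)
}

#' Content (housekeeping) scaling factors
#'
#' @return Per-sample factor: mean housekeeping sum divided by the sample's
#'   housekeeping sum. Requires exactly six housekeeping genes.
#' @rdname normalization
#' @export
content_factor <- function(counts, panel) {
  hk <- count_submatrix(counts, panel, "housekeeping")
  if (nrow(hk) != 6L) {
    stop("content normalization requires exactly 6 housekeeping genes (found ",
         nrow(hk), ")")
  }
  sums <- colSums(hk)
  if (any(sums == 0)) {
    stop("housekeeping sum is zero for sample(s): ",
         paste(colnames(counts)[sums == 0], collapse = ", "))
  }
  mean(sums) / sums
}

#' Normalize a count matrix
#'
#' @param pseudocount added before the log2 step (default 1, so a count of
#'   0 maps to 0).
#' @return For `normalize_counts()`: a list of class `normalized_matrix`
#'   with `values` (log2 scale, endogenous + housekeeping rows only),
#'   `factors` (per-sample technical/background/content), `panel` (rows of
#'   the input panel retained in `values`) and `provenance` (ordered step
#'   names).
#' @rdname normalization
#' @export
normalize_counts <- function(counts, panel, pseudocount = 1) {
  stopifnot(nrow(counts) == nrow(panel))
  tech <- technical_factor(counts, panel)
  scaled <- sweep(counts, 2, tech, `*`)
  bg <- background_level(scaled, panel)
  keep <- panel$role %in% c("endogenous", "housekeeping")
  expr <- sweep(scaled[keep, , drop = FALSE], 2, bg, `-`)
  expr[expr < 0] <- 0
  tmp <- scaled
  tmp[keep, ] <- expr
  content <- content_factor(tmp, panel)
  expr <- sweep(expr, 2, content, `*`)
  values <- log2(expr + pseudocount)
  structure(
    list(
      values = values,
      factors = data.frame(sample_id = colnames(counts), technical = tech,
                           background = bg, content = content,
                           row.names = NULL),
      panel = panel[keep, , drop = FALSE],
      provenance = c("technical_factor", "background_subtraction",
                     "content_factor", paste0("log2_pseudocount_", pseudocount))
    ),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("Normalized expression:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Per-gene z-scaling of a normalized matrix
#'
#' Centers and scales each gene across samples (used for clustering
#' distances and heat-map display; the immune ratio and MYC scoring consume
#' the log2 values directly). Genes with zero variance are left at 0.
#'
#' @param norm a `normalized_matrix` (or plain genes x samples matrix).
#' @return A genes x samples matrix of z scores.
#' @export
zscale_genes <- function(norm) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  m <- rowMeans(values)
  s <- apply(values, 1, stats::sd)
  z <- sweep(values, 1, m, `-`)
  z <- sweep(z, 1, ifelse(s > 0, s, 1), `/`)
  z
}
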