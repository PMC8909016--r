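#' @name signature_scores
#' @title Immune ratio and immunohistochemistry decision rules
#'
#' @description
#' Per-sample signature calls that need no model fitting: the immune
#' effector-to-checkpoint expression ratio with its published cutoff, the
#' Hans IHC decision tree (GCB vs non-GCB), the double-expressor rule, the
#' MYC IHC class, and the double-hit call combining FISH and NGS
#' structural-variant assays.
NULL

#' Immune effector / checkpoint expression ratio
#'
#' On log2-normalized expression the score is
#' `CD4 + CD8 - (CD163 - CD68) - PDL1`, i.e. the log2 of the linear ratio
#' `(CD4 x CD8) / ((CD163 / CD68) x PD-L1)`. A sample is immune-high iff
#' its score strictly exceeds the cutoff; the default cutoff is the
#' published value -0.278958829.
#'
#' @param expr named numeric vector, matrix (genes x samples) or
#'   `normalized_matrix` holding log2 values for the five genes.
#' @param genes named character vector mapping the roles `cd4`, `cd8`,
#'   `cd163`, `cd68`, `pdl1` to row names of `expr`.
#' @param cutoff classification cutoff on the log2 score.
#' @return `data.frame(sample_id, score, class)` with `class` in
#'   `c("high","low")`.
#' @export
immune_ratio <- function(expr,
                         genes = c(cd4 = "CD4", cd8 = "CD8A", cd163 = "CD163",
                                   cd68 = "CD68", pdl1 = "CD274"),
                         cutoff = -0.278958829) {
  values <- if (inherits(expr, "normalized_matrix")) expr$values else expr
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(names(values), "S1"))
  need <- c("cd4", "cd8", "cd163", "cd68", "pdl1")
  if (!all(need %in% names(genes))) {
    stop("genes must name all of: ", paste(need, collapse = ", "))
  }
  missing <- genes[need][!genes[need] %in% rownames(values)]
  if (length(missing) > 0) {
    stop("expression matrix is missing gene(s): ",
         paste(missing, collapse = ", "))
  }
  g <- function(role) values[genes[[role]], ]
  score <- g("cd4") + g("cd8") - (g("cd163") - g("cd68")) - g("pdl1")
  data.frame(
    sample_id = colnames(values) %||% seq_along(score),
    score = unname(score),
    class = ifelse(score > cutoff, "high", "low"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Hans IHC classification (GCB vs non-GCB)
#'
#' The decision tree on CD10, BCL6 and MUM1 staining percentages: CD10+
#' is GCB; CD10-/BCL6- is non-GCB; CD10-/BCL6+ splits on MUM1 (MUM1- GCB,
#' MUM1+ non-GCB). A marker is positive at `threshold` percent or more.
#'
#' @param cd10,bcl6,mum1 staining percentages in \[0,100\] (NA allowed;
#'   vectors are recycled to a common length).
#' @param threshold positivity threshold in percent (default 30).
#' @return Character vector: `"GCB"`, `"non-GCB"`, or `NA` when a marker
#'   required by the traversed branch is missing.
#' @export
hans_classify <- function(cd10, bcl6, mum1, threshold = 30) {
  n <- max(length(cd10), length(bcl6), length(mum1))
  cd10 <- rep_len(cd10, n); bcl6 <- rep_len(bcl6, n); mum1 <- rep_len(mum1, n)
  vapply(seq_len(n), function(i) {
    if (is.na(cd10[i])) return(NA_character_)
    if (cd10[i] >= threshold) return("GCB")
    if (is.na(bcl6[i])) return(NA_character_)
    if (bcl6[i] < threshold) return("non-GCB")
    if (is.na(mum1[i])) return(NA_character_)
    if (mum1[i] < threshold) "GCB" else "non-GCB"
  }, "")
}

#' Double-expressor call
#'
#' `TRUE` iff MYC staining is at least 40% and BCL2 staining at least 50%.
#'
#' @param myc,bcl2 staining percentages (NA gives NA).
#' @return Logical vector.
#' @export
double_expressor <- function(myc, bcl2) {
  myc >= 40 & bcl2 >= 50
}

#' MYC IHC class
#'
#' `"High"` iff MYC staining is in at least 50% of tumor cells.
#'
#' @param myc staining percentage (NA gives NA).
#' @return Character vector `"High"`/`"Low"`/NA.
#' @export
myc_ihc_class <- function(myc) {
  ifelse(is.na(myc), NA_character_, ifelse(myc >= 50, "High", "Low"))
}

#' Double-hit call from FISH and NGS structural variants
#'
#' Positive iff any observed assay is positive; not evaluable (NA) only
#' when both assays are missing.
#'
#' @param fish_positive,sv_positive logical (NA = assay not done).
#' @return Logical vector (NA where not evaluable).
#' @export
classify_dh <- function(fish_positive, sv_positive) {
  n <- max(length(fish_positive), length(sv_positive))
  fish_positive <- rep_len(fish_positive, n)
  sv_positive <- rep_len(sv_positive, n)
  out <- (!is.na(fish_positive) & fish_positive) |
    (!is.na(sv_positive) & sv_positive)
  out[is.na(fish_positive) & is.na(sv_positive)] <- NA
  # A single observed-negative assay with the other missing is negative.
  out
}
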