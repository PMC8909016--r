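#' Define a targeted expression panel
#'
#' A panel is a data frame with one row per probe, giving the probe
#' identifier, its role on the cartridge (`endogenous`, `housekeeping`,
#' `pos_control`, `neg_control`) and, for endogenous genes, which signature
#' it belongs to: the 34-gene MYC activity panel (`myc_panel`), the
#' consensus-clustering programs (`oxphos`, `bcr_prolif`, `hr`), the five
#' immune-ratio genes (`immune_cd4`, `immune_cd8`, `immune_cd163`,
#' `immune_cd68`, `immune_pdl1`), or the cell-of-origin axis (`coo`).
#'
#' @param gene_id character vector of probe identifiers (unique).
#' @param role character vector, one of `endogenous`, `housekeeping`,
#'   `pos_control`, `neg_control`.
#' @param signature character vector of signature memberships (`"none"` for
#'   genes outside every signature and for controls).
#' @return A `data.frame` of class `panel_definition`.
#' @seealso [default_panel()]
#' @export
panel_definition <- function(gene_id, role, signature) {
  stopifnot(length(gene_id) == length(role), length(role) == length(signature))
  if (anyDuplicated(gene_id)) {
    stop("panel gene identifiers must be unique")
  }
  ok_roles <- c("endogenous", "housekeeping", "pos_control", "neg_control")
  if (!all(role %in% ok_roles)) {
    stop("unknown probe role: ", paste(setdiff(role, ok_roles), collapse = ", "))
  }
  panel <- data.frame(
    gene_id = as.character(gene_id),
    role = as.character(role),
    signature = as.character(signature),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("panel_definition", "data.frame")
  panel
}

#' Validate a panel against the assay contract
#'
#' Checks the structural invariants the downstream modules rely on: exactly
#' six housekeeping genes (the RNA-content normalizer), at least one probe
#' in each control class, and exactly one gene carrying each of the five
#' immune-ratio memberships.
#'
#' @param panel a [panel_definition()].
#' @param paper_scale if `TRUE`, additionally require the study-scale
#'   signature sizes: 34 MYC-panel genes and 12/14/21 genes for the
#'   OxPhos / BCR-proliferation / host-response programs.
#' @return `invisible(TRUE)` or an error describing the violation.
#' @export
validate_panel <- function(panel, paper_scale = FALSE) {
  stopifnot(inherits(panel, "data.frame"))
  n_hk <- sum(panel$role == "housekeeping")
  if (n_hk != 6L) {
    stop("panel must contain exactly 6 housekeeping genes (found ", n_hk, ")")
  }
  if (!any(panel$role == "pos_control")) stop("panel has no positive-control probes")
  if (!any(panel$role == "neg_control")) stop("panel has no negative-control probes")
  for (s in c("immune_cd4", "immune_cd8", "immune_cd163", "immune_cd68", "immune_pdl1")) {
    if (sum(panel$signature == s) != 1L) {
      stop("signature ", s, " must be carried by exactly one gene")
    }
  }
  if (paper_scale) {
    sizes <- c(myc_panel = 34L, oxphos = 12L, bcr_prolif = 14L, hr = 21L)
    for (s in names(sizes)) {
      got <- sum(panel$signature == s)
      if (got != sizes[[s]]) {
        stop("study-scale panel requires ", sizes[[s]], " ", s,
             " genes (found ", got, ")")
      }
    }
  }
  invisible(TRUE)
}

#' The default 117-gene study-scale panel
#'
#' A synthetic stand-in for the targeted DLBCL panel: 117 genes comprising
#' the 34-gene MYC activity panel, 12 OxPhos, 14 BCR/proliferation and 21
#' host-response consensus-cluster genes, the five immune-ratio genes
#' (CD4, CD8A, CD163, CD68, CD274), 25 cell-of-origin axis genes and 6
#' housekeeping genes, plus 6 positive-control (ladder) and 8
#' negative-control probes. Identifiers other than the named immune and
#' housekeeping genes are synthetic placeholders; the real panel membership
#' is proprietary configuration, not something this package derives.
#'
#' @return A [panel_definition()] passing [validate_panel()] at study scale.
#' @export
default_panel <- function() {
  pad2 <- function(i) formatC(i, width = 2, flag = "0")
  myc <- c("MYC", paste0("MYCTGT_", pad2(2:34)))
  oxp <- paste0("OXPHOS_", pad2(1:12))
  bcr <- paste0("BCRPRO_", pad2(1:14))
  hr <- paste0("HOSTR_", pad2(1:21))
  imm <- c("CD4", "CD8A", "CD163", "CD68", "CD274")
  coo <- paste0("COOAX_", pad2(1:25))
  hk <- c("ACTB", "GUSB", "POLR2A", "SDHA", "TBP", "TUBB")
  pos <- paste0("POS_", LETTERS[1:6])
  neg <- paste0("NEG_", LETTERS[1:8])

  panel_definition(
    gene_id = c(myc, oxp, bcr, hr, imm, coo, hk, pos, neg),
    role = c(
      rep("endogenous", length(myc) + length(oxp) + length(bcr) +
            length(hr) + length(imm) + length(coo)),
      rep("housekeeping", 6L),
      rep("pos_control", 6L),
      rep("neg_control", 8L)
    ),
    signature = c(
      rep("myc_panel", 34L), rep("oxphos", 12L), rep("bcr_prolif", 14L),
      rep("hr", 21L),
      c("immune_cd4", "immune_cd8", "immune_cd163", "immune_cd68", "immune_pdl1"),
      rep("coo", 25L), rep("none", 6L + 6L + 8L)
    )
  )
}

# Gene ids for a signature (or set of signatures).
panel_genes <- function(panel, signatures) {
  panel$gene_id[panel$signature %in% signatures]
}
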