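#' Log2 of a raw fold change
#'
#' The differential-expression gate of 1.3-fold corresponds to a log2 fold
#' change of 0.3785.
#'
#' @param raw_fold positive fold-change ratio.
#' @return log2 units.
#' @export
log2fc_of_fold <- function(raw_fold) {
  if (any(raw_fold <= 0)) stop("raw fold change must be positive")
  log2(raw_fold)
}

#' Differential-expression thresholds
#'
#' Defaults: |log2 FC| >= 0.3785 (raw fold 1.3), adjusted p <= 0.05, mean
#' control expression > 0.1 FPKM, and exclusion of the knocked-out gene(s)
#' plus the artefactually up-regulated Plekhg2. For the triple-knockout
#' contrast pass all three family genes in `excluded_genes`.
#'
#' @param min_abs_log2fc magnitude gate on log2 fold change.
#' @param max_padj adjusted-p ceiling.
#' @param min_control_fpkm control expression floor.
#' @param excluded_genes identifiers/symbols dropped before thresholding.
#' @return list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(min_abs_log2fc = log2fc_of_fold(1.3),
                           max_padj = 0.05,
                           min_control_fpkm = 0.1,
                           excluded_genes = c("Zfp36", "Plekhg2")) {
  stopifnot(min_abs_log2fc > 0, max_padj > 0, min_control_fpkm >= 0)
  structure(list(min_abs_log2fc = min_abs_log2fc, max_padj = max_padj,
                 min_control_fpkm = min_control_fpkm,
                 excluded_genes = excluded_genes),
            class = "deg_thresholds")
}

#' Apply differential-expression thresholds to a result table
#'
#' `up = {log2fc >= +gate & padj <= max & control_mean > floor & not
#' excluded}`; `down` symmetric with `log2fc <= -gate`. The magnitude gate is
#' two-sided, with the sign assigning up/down. The report lists why each
#' non-passing gene was excluded.
#'
#' @param table data frame with `gene_id`, `log2fc`, `padj`, `control_mean`
#'   (as from [read_deg_table()]).
#' @param thresholds a [deg_thresholds()].
#' @return list: `up` and `down` (character vectors of gene identifiers) and
#'   `excluded` (data frame `gene_id`, `reason`).
#' @export
apply_deg_thresholds <- function(table, thresholds = deg_thresholds()) {
  req <- c("gene_id", "log2fc", "padj", "control_mean")
  if (!all(req %in% names(table)))
    stop("missing columns: ", paste(setdiff(req, names(table)), collapse = ", "))
  th <- thresholds
  excluded <- table$gene_id %in% th$excluded_genes
  low <- !excluded & (is.na(table$control_mean) |
                        table$control_mean <= th$min_control_fpkm)
  ns_p <- is.na(table$padj) | table$padj > th$max_padj
  small <- is.na(table$log2fc) | abs(table$log2fc) < th$min_abs_log2fc
  ok <- !excluded & !low & !ns_p & !small
  up <- table$gene_id[ok & table$log2fc > 0]
  down <- table$gene_id[ok & table$log2fc < 0]
  reason <- rep(NA_character_, nrow(table))
  reason[small] <- "below_fold_threshold"
  reason[ns_p] <- "padj_above_threshold"
  reason[low] <- "low_expression"
  reason[excluded] <- "excluded_gene"
  excluded_report <- data.frame(gene_id = table$gene_id[!ok],
                                reason = reason[!ok],
                                stringsAsFactors = FALSE)
  list(up = up, down = down, excluded = excluded_report)
}

#' Two-set overlap (Venn) decomposition
#'
#' @param setA,setB character vectors (duplicates ignored).
#' @return list: `counts` (named `a_only`, `b_only`, `both`) and the three
#'   membership vectors.
#' @export
overlap_sets <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  both <- intersect(setA, setB)
  a_only <- setdiff(setA, setB)
  b_only <- setdiff(setB, setA)
  list(counts = c(a_only = length(a_only), b_only = length(b_only),
                  both = length(both)),
       a_only = a_only, b_only = b_only, both = both)
}

#' Flag previously identified targets in a gene set
#'
#' Identifiers are matched case-insensitively against the supplied list of
#' known targets (the package ships no curated biology).
#'
#' @param genes character vector of gene identifiers or symbols.
#' @param known_targets user-supplied character vector.
#' @return data frame `gene_id`, `known_target`, with attribute `fraction`.
#' @export
flag_known_targets <- function(genes, known_targets) {
  if (!length(known_targets)) {
    warning("empty known-target list; all flags FALSE")
    flags <- rep(FALSE, length(genes))
  } else {
    flags <- tolower(genes) %in% tolower(known_targets)
  }
  out <- data.frame(gene_id = genes, known_target = flags,
                    stringsAsFactors = FALSE)
  attr(out, "fraction") <- if (length(genes)) mean(flags) else NA_real_
  out
}
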