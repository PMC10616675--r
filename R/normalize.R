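#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed against the geometric-mean reference
#' profile, using only genes with nonzero counts in every sample, then
#' normalized to geometric mean 1.
#'
#' @param counts gene x sample matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) stop("no gene has nonzero counts in all samples")
  logc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- exp(apply(logc - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Normalized counts per kilobase
#'
#' `count / size_factor / (length_bp / 1000)` — the per-kilobase expression
#' unit used throughout the decay analysis.
#'
#' @param counts gene x sample matrix.
#' @param lengths named gene lengths in bp (> 0), covering all genes in
#'   `counts`.
#' @param factors per-sample size factors, as from [size_factors()].
#' @return matrix of the same shape as `counts`.
#' @export
normalized_per_kb <- function(counts, lengths, factors = size_factors(counts)) {
  if (!is.null(names(lengths))) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing))
      stop("length missing for genes: ", paste(utils::head(missing, 5), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(all(lengths > 0), length(factors) == ncol(counts))
  sweep(counts, 2, factors, `/`) / (lengths / 1000)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `count * 1e9 / (column_sum * length_bp)`; used only as the expression floor
#' (mean control FPKM > 0.1 at the anchor timepoint).
#'
#' @inheritParams normalized_per_kb
#' @return matrix of the same shape as `counts`.
#' @export
fpkm <- function(counts, lengths) {
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  stopifnot(all(lengths > 0))
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("empty library")
  sweep(counts, 2, libsize, `/`) * 1e9 / lengths
}

#' Per-replicate percent-remaining decay curves
#'
#' Converts normalized expression to the percentage of the same subject's
#' anchor (t = 0) value: `P_g(t) = 100 * x_g(t) / x_g(0)`. Subjects with a
#' zero anchor value yield missing percents for that gene. Values above 100
#' are permitted (the renormalization-artifact regime). With
#' `anchor = "genotype_mean"` all subjects of a genotype share the genotype
#' mean anchor instead (for unpaired layouts).
#'
#' @param normalized gene x sample matrix of normalized expression.
#' @param samples sample sheet (`sample_id`, `genotype`, `subject`,
#'   `time_min`) covering the columns of `normalized`.
#' @param anchor `"subject"` (default; each mouse's own t = 0) or
#'   `"genotype_mean"`.
#' @return object of class `percent_remaining_curves`: the percent matrix,
#'   the sample sheet, and per-(gene, genotype, timepoint) means and SDs
#'   across subjects.
#' @export
percent_remaining <- function(normalized, samples, anchor = c("subject", "genotype_mean")) {
  anchor <- match.arg(anchor)
  stopifnot(setequal(colnames(normalized), samples$sample_id))
  samples <- samples[match(colnames(normalized), samples$sample_id), ]
  t0 <- samples$time_min == 0
  subj_t0 <- samples$sample_id[t0]
  names(subj_t0) <- samples$subject[t0]
  missing_anchor <- setdiff(unique(samples$subject), names(subj_t0))
  if (length(missing_anchor))
    stop("subject missing its t = 0 anchor sample: ",
         paste(missing_anchor, collapse = ", "))
  if (anchor == "subject") {
    x0 <- normalized[, subj_t0[samples$subject], drop = FALSE]
  } else {
    geno_t0 <- vapply(unique(samples$genotype), function(g) {
      cols <- samples$sample_id[t0 & samples$genotype == g]
      rowMeans(normalized[, cols, drop = FALSE])
    }, numeric(nrow(normalized)))
    x0 <- geno_t0[, samples$genotype, drop = FALSE]
  }
  pct <- 100 * normalized / x0
  pct[x0 == 0] <- NA_real_
  dimnames(pct) <- dimnames(normalized)

  times <- sort(unique(samples$time_min))
  genos <- unique(samples$genotype)
  mean_arr <- sd_arr <- n_arr <- list()
  for (g in genos) {
    mg <- sg <- ng <- matrix(NA_real_, nrow(pct), length(times),
                             dimnames = list(rownames(pct), times))
    for (j in seq_along(times)) {
      cols <- samples$sample_id[samples$genotype == g & samples$time_min == times[j]]
      block <- pct[, cols, drop = FALSE]
      ng[, j] <- rowSums(!is.na(block))
      mg[, j] <- rowMeans(block, na.rm = TRUE)
      sg[, j] <- apply(block, 1, stats::sd, na.rm = TRUE)
    }
    mg[ng[, ] == 0] <- NA_real_
    mean_arr[[g]] <- mg; sd_arr[[g]] <- sg; n_arr[[g]] <- ng
  }
  structure(list(percent = pct, samples = samples, timepoints = times,
                 genotypes = genos, mean = mean_arr, sd = sd_arr, n = n_arr,
                 anchor = anchor),
            class = "percent_remaining_curves")
}

#' @export
print.percent_remaining_curves <- function(x, ...) {
  cat("percent_remaining_curves:", nrow(x$percent), "genes,",
      length(x$genotypes), "genotypes, timepoints (min):",
      paste(x$timepoints, collapse = ", "),
      sprintf("(anchor: %s)\n", x$anchor))
  invisible(x)
}

#' Long-format view of percent-remaining curves
#' @param curves a `percent_remaining_curves` object.
#' @return data frame: `gene_id`, `genotype`, `subject`, `time_min`,
#'   `percent`.
#' @export
curves_long <- function(curves) {
  s <- curves$samples
  data.frame(
    gene_id = rep(rownames(curves$percent), times = nrow(s)),
    genotype = rep(s$genotype, each = nrow(curves$percent)),
    subject = rep(s$subject, each = nrow(curves$percent)),
    time_min = rep(s$time_min, each = nrow(curves$percent)),
    percent = as.vector(curves$percent),
    stringsAsFactors = FALSE)
}

#' Percent-remaining per-subject matrices for one genotype and timepoint
#' @noRd
subject_percents <- function(curves, genotype, time) {
  s <- curves$samples
  cols <- s$sample_id[s$genotype == genotype & s$time_min == time]
  curves$percent[, cols, drop = FALSE]
}

#' Filter cascade preceding the stabilization screen
#'
#' A gene is retained iff it has an mRNA biotype, is not on the exclusion
#' list (by default the knocked-out gene family and the artefactually
#' up-regulated Plekhg2), its mean control FPKM at the anchor timepoint is at
#' least `min_fpkm`, its mean control percent remaining at `ceiling_time`
#' minutes has dropped below `decay_ceiling`, and its anchor value is defined
#' for at least one control subject. Reasons are computed on the full input
#' (not sequentially), so the report is order-independent and a gene can
#' carry several reasons.
#'
#' @param curves a `percent_remaining_curves` object.
#' @param fpkm_matrix gene x sample FPKM matrix.
#' @param annotation gene annotation data frame (`gene_id`, `biotype`, ...).
#' @param control_genotype label of the control genotype.
#' @param excluded_genes identifiers or symbols to drop.
#' @param min_fpkm expression floor (default 0.1 FPKM).
#' @param decay_ceiling percent-remaining ceiling (default 85).
#' @param ceiling_time minutes at which the ceiling is evaluated (default
#'   120); if absent from the grid the latest timepoint before it is used,
#'   with a message.
#' @param mrna_biotypes biotype labels treated as mRNA.
#' @return data frame of class `filter_report`: `gene_id`, `retained`,
#'   `reasons` (list column with entries from `non_mrna`, `excluded_gene`,
#'   `low_expression`, `non_decaying_control`, `undefined_t0`).
#' @export
apply_filters <- function(curves, fpkm_matrix, annotation,
                          control_genotype = curves$genotypes[1],
                          excluded_genes = c("Zfp36", "Zfp36l1", "Zfp36l2", "Plekhg2"),
                          min_fpkm = 0.1, decay_ceiling = 85,
                          ceiling_time = 120,
                          mrna_biotypes = c("protein_coding", "mRNA")) {
  genes <- rownames(curves$percent)
  ann <- annotation[match(genes, annotation$gene_id), ]
  s <- curves$samples

  times <- curves$timepoints
  if (!ceiling_time %in% times) {
    eligible <- times[times <= ceiling_time & times > 0]
    if (!length(eligible)) stop("no timepoint at or before ceiling_time")
    message("ceiling_time ", ceiling_time, " not on the grid; using ",
            max(eligible), " min")
    ceiling_time <- max(eligible)
  }

  ctrl_t0 <- s$sample_id[s$genotype == control_genotype & s$time_min == 0]
  mean_ctrl_fpkm <- rowMeans(fpkm_matrix[genes, ctrl_t0, drop = FALSE])
  ctrl_mean_ceiling <- curves$mean[[control_genotype]][, as.character(ceiling_time)]

  non_mrna <- !(ann$biotype %in% mrna_biotypes)
  excluded <- ann$gene_id %in% excluded_genes | ann$symbol %in% excluded_genes
  low_expr <- mean_ctrl_fpkm < min_fpkm
  undefined_t0 <- is.na(ctrl_mean_ceiling)
  non_decaying <- !undefined_t0 & ctrl_mean_ceiling >= decay_ceiling

  reasons <- lapply(seq_along(genes), function(i) {
    r <- character(0)
    if (non_mrna[i]) r <- c(r, "non_mrna")
    if (excluded[i]) r <- c(r, "excluded_gene")
    if (low_expr[i]) r <- c(r, "low_expression")
    if (non_decaying[i]) r <- c(r, "non_decaying_control")
    if (undefined_t0[i]) r <- c(r, "undefined_t0")
    r
  })
  out <- data.frame(gene_id = genes,
                    retained = lengths(reasons) == 0,
                    stringsAsFactors = FALSE)
  out$reasons <- reasons
  class(out) <- c("filter_report", "data.frame")
  out
}
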