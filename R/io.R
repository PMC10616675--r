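#' Container for one genotype-pair chase study
#'
#' Bundles a gene x sample count matrix with its gene annotation and sample
#' sheet, validating that samples and genes agree across the three tables and
#' that no (genotype, subject) pair has more than one library per timepoint.
#' `time_min = 0` denotes the anchor sample taken at actinomycin-D addition
#' (1 h after LPS).
#'
#' @param counts numeric gene x sample matrix, non-negative; integer when read
#'   from disk, possibly fractional for noise-free simulations.
#' @param gene_annotation data frame with columns `gene_id`, `symbol`,
#'   `biotype`, `length_bp` (bp > 0).
#' @param sample_sheet data frame with columns `sample_id`, `genotype`,
#'   `subject`, `time_min`.
#' @return a list of class `chase_experiment`.
#' @export
chase_experiment <- function(counts, gene_annotation, sample_sheet) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene identifiers in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample identifiers in counts")
  req_ann <- c("gene_id", "symbol", "biotype", "length_bp")
  if (!all(req_ann %in% names(gene_annotation)))
    stop("gene_annotation missing required columns: ",
         paste(setdiff(req_ann, names(gene_annotation)), collapse = ", "))
  req_ss <- c("sample_id", "genotype", "subject", "time_min")
  if (!all(req_ss %in% names(sample_sheet)))
    stop("sample_sheet missing required columns: ",
         paste(setdiff(req_ss, names(sample_sheet)), collapse = ", "))
  if (!setequal(rownames(counts), gene_annotation$gene_id) ||
      anyDuplicated(gene_annotation$gene_id))
    stop("genes in counts and gene_annotation must be a bijection")
  if (!setequal(colnames(counts), sample_sheet$sample_id) ||
      anyDuplicated(sample_sheet$sample_id))
    stop("samples in counts and sample_sheet must be a bijection")
  if (any(gene_annotation$length_bp <= 0))
    stop("gene lengths must be strictly positive")
  key <- paste(sample_sheet$genotype, sample_sheet$subject,
               sample_sheet$time_min)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    offenders <- sample_sheet$sample_id[key == dup]
    stop("more than one sample per (genotype, subject, timepoint): ",
         paste(offenders, collapse = ", "))
  }
  gene_annotation <- gene_annotation[match(rownames(counts),
                                           gene_annotation$gene_id), ,
                                     drop = FALSE]
  rownames(gene_annotation) <- NULL
  sample_sheet <- sample_sheet[match(colnames(counts),
                                     sample_sheet$sample_id), , drop = FALSE]
  rownames(sample_sheet) <- NULL
  structure(list(counts = counts, gene_annotation = gene_annotation,
                 sample_sheet = sample_sheet),
            class = "chase_experiment")
}

#' @export
print.chase_experiment <- function(x, ...) {
  cat("chase_experiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n  genotypes:",
      paste(unique(x$sample_sheet$genotype), collapse = ", "),
      "\n  timepoints (min):",
      paste(sort(unique(x$sample_sheet$time_min)), collapse = ", "), "\n")
  invisible(x)
}

read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required columns: ", paste(missing, collapse = ", "))
  df
}

#' Read a gene x sample count matrix from TSV
#'
#' First column must be `gene_id`; every other column is a sample. Counts must
#' be non-negative integers; malformed entries are reported with their line
#' number (header = line 1).
#'
#' @param path file path.
#' @param sep field separator; `"\t"` default, `","` accepted.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, sep = "\t") {
  df <- read_table_checked(path, "gene_id", sep)
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicated gene identifiers: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric count entries")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(path, ": counts must be non-negative integers; offending lines: ",
         paste(unique(bad[, 1] + 1L), collapse = ", "))
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Read a gene annotation table (gene_id, symbol, biotype, length_bp)
#' @param path file path.
#' @param sep field separator.
#' @return data frame.
#' @export
read_gene_annotation <- function(path, sep = "\t") {
  df <- read_table_checked(path, c("gene_id", "symbol", "biotype", "length_bp"), sep)
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicated gene identifiers")
  bad <- which(is.na(df$length_bp) | df$length_bp <= 0)
  if (length(bad))
    stop(path, ": non-positive or missing length_bp at lines: ",
         paste(bad + 1L, collapse = ", "))
  df
}

#' Read a sample sheet (sample_id, genotype, subject, time_min)
#' @param path file path.
#' @param sep field separator.
#' @return data frame.
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  df <- read_table_checked(path, c("sample_id", "genotype", "subject", "time_min"), sep)
  tm <- suppressWarnings(as.numeric(df$time_min))
  bad <- which(is.na(tm) | tm < 0)
  if (length(bad))
    stop(path, ": time_min not a non-negative number at lines: ",
         paste(bad + 1L, collapse = ", "))
  df$time_min <- tm
  key <- paste(df$genotype, df$subject, df$time_min)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(path, ": duplicate (genotype, subject, time) for samples: ",
         paste(df$sample_id[key == dup], collapse = ", "))
  }
  df
}

#' Read a differential-expression result table
#'
#' Expects columns `gene_id`, `log2fc`, `padj`, `control_mean` (mean control
#' expression in per-kilobase normalized units). `padj` must lie in [0, 1] or
#' be missing.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data frame.
#' @export
read_deg_table <- function(path, sep = "\t") {
  df <- read_table_checked(path, c("gene_id", "log2fc", "padj", "control_mean"), sep)
  if (anyDuplicated(df$gene_id)) stop(path, ": duplicated gene identifiers")
  bad <- which(!is.na(df$padj) & (df$padj < 0 | df$padj > 1))
  if (length(bad))
    stop(path, ": padj outside [0, 1] at lines: ", paste(bad + 1L, collapse = ", "))
  df
}

#' Read 3'-UTR sequences from FASTA
#'
#' Accepts wrapped or unwrapped records, mixed case, and DNA or RNA alphabet;
#' sequences are returned uppercase in the RNA alphabet (T mapped to U).
#' Repeated identifiers are allowed (multiple UTR isoform records per gene).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    stop(path, ": illegal characters in records: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- NA
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a count matrix as TSV (gene_id + one column per sample)
#' @param counts gene x sample matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write UTR sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_utr_fasta <- function(sequences, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write the screen output tables
#'
#' Emits three TSVs under `dir`: `screen_table.tsv` (one row per retained
#' gene, mirroring the published supplementary layout: identity, binding-site
#' and known-target flags, per-timepoint mean/SD percent remaining for both
#' genotypes, per-timepoint t-test p-values, the qualifying consecutive
#' window, ANOVA term p-values with the Greenhouse-Geisser epsilon, rank
#' metric, half-lives, and the stabilized call), `filter_report.tsv`
#' (gene_id, retained, semicolon-joined reasons) and `curves.tsv`
#' (long format: gene_id, genotype, subject, time_min, percent).
#'
#' @param result a `screen_result` from [run_screen()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_screen_tables <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(screen = file.path(dir, "screen_table.tsv"),
             filter = file.path(dir, "filter_report.tsv"),
             curves = file.path(dir, "curves.tsv"))
  write_tsv(result$table, paths["screen"])
  fr <- result$filter_report
  fr$reasons <- vapply(fr$reasons, paste, character(1), collapse = ";")
  write_tsv(fr, paths["filter"])
  write_tsv(curves_long(result$curves), paths["curves"])
  invisible(paths)
}

#' Read back a screen table written by [write_screen_tables()]
#' @param path path to `screen_table.tsv`.
#' @return data frame with the same columns and types as the written table.
#' @export
read_screen_table <- function(path) {
  df <- read_table_checked(path, c("gene_id", "stabilized"))
  for (col in c("stage1_pass", "stage2_pass", "stabilized"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}
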