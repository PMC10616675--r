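#' TTP-family binding-site motif classes
#'
#' The four AU-rich element patterns scanned in 3'-UTRs: UAUUUAU (7-mer),
#' UAUUUUAU (8-mer), UUAUUUAUU (9-mer), UUAUUUUAUU (10-mer). By construction
#' the 9-mer contains the 7-mer at offset 2 and the 10-mer contains the 8-mer
#' at offset 2, so longer hits always imply shorter ones inside them.
#'
#' @return data frame with columns `class`, `pattern`, `length`.
#' @export
ttp_motif_classes <- function() {
  data.frame(class = c("7-mer", "8-mer", "9-mer", "10-mer"),
             pattern = c("UAUUUAU", "UAUUUUAU", "UUAUUUAUU", "UUAUUUUAUU"),
             length = c(7L, 8L, 9L, 10L),
             stringsAsFactors = FALSE)
}

normalize_rna <- function(sequence) {
  s <- chartr("T", "U", toupper(sequence))
  if (grepl("[^ACGUN]", s)) stop("illegal characters in sequence")
  s
}

#' Scan one sequence for AU-rich binding sites
#'
#' Reports all occurrences of each motif class, overlapping occurrences
#' included, with 1-based inclusive coordinates on the given (sense) strand.
#' U and T are equivalent and case is ignored; N never matches. The maximal
#' view keeps only hits not wholly contained in a longer hit.
#'
#' @param sequence nucleotide string over A, C, G, U/T, N (any case).
#' @param classes motif classes, as from [ttp_motif_classes()].
#' @return list of class `site_annotation`: `hits` (data frame
#'   `motif_class`, `start`, `end`), `counts` (named per class), `has_site`,
#'   `maximal` (subset of `hits`).
#' @export
scan_sequence <- function(sequence, classes = ttp_motif_classes()) {
  s <- normalize_rna(sequence)
  hits <- lapply(seq_len(nrow(classes)), function(i) {
    # lookahead so overlapping occurrences are all found
    m <- gregexpr(paste0("(?=", classes$pattern[i], ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(motif_class = classes$class[i], start = as.integer(m),
               end = as.integer(m) + classes$length[i] - 1L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(motif_class = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  counts <- stats::setNames(
    vapply(classes$class, function(cl) sum(hits$motif_class == cl), integer(1)),
    classes$class)
  maximal <- hits[vapply(seq_len(nrow(hits)), function(i) {
    w <- hits$end[i] - hits$start[i]
    !any(hits$start <= hits$start[i] & hits$end >= hits$end[i] &
           (hits$end - hits$start) > w)
  }, logical(1)), , drop = FALSE]
  structure(list(hits = hits, counts = counts,
                 has_site = nrow(hits) > 0, maximal = maximal),
            class = "site_annotation")
}

#' @export
print.site_annotation <- function(x, ...) {
  cat("site_annotation:", nrow(x$hits), "hits (",
      paste(names(x$counts), x$counts, collapse = ", "), ")\n")
  invisible(x)
}

#' Scan a set of UTR sequences
#'
#' One annotation per gene. When several UTR isoform records share an
#' identifier, hits are unioned (a record index distinguishes positions) and
#' `has_site` is true if any record has a hit.
#'
#' @param utrs named character vector of sequences (names may repeat across
#'   isoform records of a gene).
#' @param classes motif classes.
#' @return named list of `site_annotation` objects, one per unique gene.
#' @export
annotate_gene_set <- function(utrs, classes = ttp_motif_classes()) {
  if (length(utrs) == 0) return(stats::setNames(list(), character(0)))
  stopifnot(!is.null(names(utrs)))
  genes <- unique(names(utrs))
  out <- lapply(genes, function(g) {
    records <- which(names(utrs) == g)
    anns <- lapply(seq_along(records), function(ri) {
      a <- scan_sequence(utrs[[records[ri]]], classes)
      if (nrow(a$hits)) a$hits$record <- ri else a$hits$record <- integer(0)
      a
    })
    hits <- do.call(rbind, lapply(anns, `[[`, "hits"))
    counts <- Reduce(`+`, lapply(anns, `[[`, "counts"))
    maximal <- do.call(rbind, lapply(anns, function(a) {
      m <- a$maximal
      if (nrow(m)) m$record <- a$hits$record[match(
        paste(m$motif_class, m$start), paste(a$hits$motif_class, a$hits$start))]
      m
    }))
    structure(list(hits = hits, counts = counts,
                   has_site = nrow(hits) > 0, maximal = maximal),
              class = "site_annotation")
  })
  stats::setNames(out, genes)
}

#' Fraction of a gene set with at least one binding site
#'
#' Genes missing from the annotation are counted as siteless and reported via
#' a message.
#'
#' @param genes character vector of gene identifiers (non-empty).
#' @param annotation result of [annotate_gene_set()].
#' @return fraction in [0, 1].
#' @export
site_fraction <- function(genes, annotation) {
  if (!length(genes)) stop("empty gene set")
  covered <- genes %in% names(annotation)
  if (any(!covered))
    message(sum(!covered), " genes missing from annotation, counted as no-site")
  has <- vapply(genes[covered], function(g) annotation[[g]]$has_site, logical(1))
  sum(has) / length(genes)
}

#' Per-gene binding-site summary table
#' @param annotation result of [annotate_gene_set()].
#' @return data frame: `gene_id`, `n7`, `n8`, `n9`, `n10`, `has_site`.
#' @export
site_summary_table <- function(annotation) {
  cls <- ttp_motif_classes()$class
  data.frame(gene_id = names(annotation),
             n7 = vapply(annotation, function(a) a$counts[["7-mer"]], integer(1)),
             n8 = vapply(annotation, function(a) a$counts[["8-mer"]], integer(1)),
             n9 = vapply(annotation, function(a) a$counts[["9-mer"]], integer(1)),
             n10 = vapply(annotation, function(a) a$counts[["10-mer"]], integer(1)),
             has_site = vapply(annotation, `[[`, logical(1), "has_site"),
             row.names = NULL, stringsAsFactors = FALSE)
}
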