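# Shared fixtures and independent oracles for the test suite.

# Naive exhaustive substring scanner: the independent oracle for the motif
# scanner. Compares every window of the (normalized) sequence against every
# pattern.
naive_scan <- function(sequence, classes = ttp_motif_classes()) {
  s <- chartr("T", "U", toupper(sequence))
  hits <- NULL
  for (i in seq_len(nrow(classes))) {
    w <- classes$length[i]
    if (nchar(s) < w) next
    for (st in seq_len(nchar(s) - w + 1L)) {
      if (substr(s, st, st + w - 1L) == classes$pattern[i])
        hits <- rbind(hits, data.frame(motif_class = classes$class[i],
                                       start = st, end = st + w - 1L,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits))
    hits <- data.frame(motif_class = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Random sequence with mixed case and mixed U/T alphabet, AU-rich so motif
# hits actually occur.
random_au_rich_seq <- function(len = 200) {
  chars <- sample(c("A", "a", "U", "u", "T", "t", "G", "g", "C", "c"), len,
                  replace = TRUE,
                  prob = c(.2, .2, .1, .1, .1, .1, .05, .05, .05, .05))
  paste(chars, collapse = "")
}

# Build a percent_remaining_curves object from per-genotype arrays of percent
# values (gene x subject x time, with time 1 being the anchor at 100).
curves_from_percent <- function(percent_list, times,
                                gene_ids = NULL) {
  genos <- names(percent_list)
  n_gene <- dim(percent_list[[1]])[1]
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n_gene))
  cols <- list(); samp <- NULL
  for (g in genos) {
    arr <- percent_list[[g]]
    for (s in seq_len(dim(arr)[2])) {
      for (ti in seq_along(times)) {
        id <- sprintf("%s_m%d_t%03d", g, s, times[ti])
        cols[[id]] <- arr[, s, ti]
        samp <- rbind(samp, data.frame(sample_id = id, genotype = g,
                                       subject = paste0(g, "_m", s),
                                       time_min = times[ti],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  norm <- do.call(cbind, cols)
  rownames(norm) <- gene_ids
  percent_remaining(norm, samp)
}

# Small noisy two-genotype fixture: control decays with the given half-life,
# knockout with another; gaussian noise on the percent scale.
noisy_decay_percents <- function(n_gene, hl_ctrl, hl_ko,
                                 times = c(0, 15, 30, 45, 60, 90, 120),
                                 n_sub = 4, sd = 2, seed = 1) {
  set.seed(seed)
  mk <- function(hl) {
    arr <- array(0, dim = c(n_gene, n_sub, length(times)))
    for (ti in seq_along(times)) {
      mu <- 100 * exp(-log(2) / hl * times[ti])
      arr[, , ti] <- mu + if (times[ti] == 0) 0 else
        stats::rnorm(n_gene * n_sub, 0, sd)
    }
    arr
  }
  list(control = mk(hl_ctrl), ko = mk(hl_ko))
}

default_grid <- c(0, 15, 30, 45, 60, 90, 120)

# Per-subject percent columns for one genotype and timepoint.
subject_percents_for_test <- function(curves, genotype, time) {
  s <- curves$samples
  cols <- s$sample_id[s$genotype == genotype & s$time_min == time]
  curves$percent[, cols, drop = FALSE]
}
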