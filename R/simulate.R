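#' Configuration for a synthetic actinomycin-D chase experiment
#'
#' Describes the generative model for a two-genotype transcription-shutoff
#' (actinomycin D) chase: gene-specific exponential decay, negative-binomial
#' replicate noise with one library per mouse per timepoint, and (optionally)
#' a fixed-total-depth renormalization that reproduces the apparent-increase
#' artifact for slow-decaying transcripts.
#'
#' Baseline (t = 0) expected abundances are log-normal. The control half-life
#' distribution is a fast/slow mixture reflecting a chase transcriptome in
#' which most mRNAs are long-lived: a fraction `fast_fraction` of mRNA genes
#' draw log-uniform half-lives from `control_halflife_range` minutes (the
#' screen's targets), the rest draw from `slow_halflife_range`, and a
#' fraction `nondecaying_fraction` have decay rate 0 (infinite half-life) in
#' all genotypes. A fraction `stabilized_fraction` of genes -- drawn from the
#' fast class, whose decay the screen can resolve -- get their half-life
#' multiplied by `stabilization_factor` in the knockout genotype(s);
#' `stabilized_control_halflife`, when given, pins their control half-life
#' (e.g. 20 min). A fraction `nonmrna_fraction` of genes are tagged with
#' non-mRNA biotypes so the biotype filter has work to do.
#'
#' @param n_genes number of genes to simulate.
#' @param genotypes character vector of genotype labels; the first is the
#'   control.
#' @param n_subjects_per_genotype number of mice per genotype (default 4).
#' @param timepoints_min strictly increasing minutes after actinomycin D,
#'   starting at 0 (the 1-h-LPS anchor sample).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   expected t = 0 abundance (arbitrary expression units).
#' @param control_halflife_range range (minutes) of the log-uniform half-life
#'   distribution of fast-decaying control mRNAs.
#' @param fast_fraction proportion of mRNA genes in the fast-decay class.
#' @param slow_halflife_range range (minutes) of the log-uniform half-life
#'   distribution of the slow (long-lived) class.
#' @param stabilized_fraction proportion of genes stabilized in the knockout
#'   genotype(s); drawn from the fast class.
#' @param stabilized_control_halflife optional fixed control half-life
#'   (minutes) for stabilized genes; `NULL` draws from the fast distribution.
#' @param stabilization_factor multiplier (> 1) applied to the control
#'   half-life in the knockout for stabilized genes.
#' @param nondecaying_fraction proportion of genes with decay rate 0 in all
#'   genotypes.
#' @param nonmrna_fraction proportion of genes tagged with non-mRNA biotypes.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2). Must be >= 0; 0 switches noise off, in which case exact expected
#'   abundances (possibly non-integer) are emitted.
#' @param library_depth expected total counts per library at t = 0.
#' @param renormalize_to_fixed_depth if `TRUE`, every library is rescaled so
#'   its column sum equals `library_depth`; this is what creates the artifact
#'   whereby non-decaying transcripts appear to increase.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a list of class `decay_sim_config`.
#' @export
decay_sim_config <- function(n_genes = 2000L,
                             genotypes = c("control", "ko"),
                             n_subjects_per_genotype = 4L,
                             timepoints_min = c(0, 15, 30, 45, 60, 90, 120),
                             baseline_meanlog = log(200),
                             baseline_sdlog = 1,
                             control_halflife_range = c(15, 60),
                             fast_fraction = 0.35,
                             slow_halflife_range = c(300, 1000),
                             stabilized_fraction = 0.025,
                             stabilized_control_halflife = NULL,
                             stabilization_factor = 6,
                             nondecaying_fraction = 0.05,
                             nonmrna_fraction = 0.05,
                             dispersion = 0.01,
                             library_depth = 2e6,
                             renormalize_to_fixed_depth = TRUE,
                             seed = 1L) {
  if (length(timepoints_min) < 2 || any(diff(timepoints_min) <= 0))
    stop("timepoints_min must be strictly increasing")
  if (timepoints_min[1] != 0)
    stop("timepoints_min must start at 0 (the anchor sample)")
  if (n_subjects_per_genotype < 1) stop("need at least one subject per genotype")
  if (length(genotypes) < 2) stop("need a control and at least one knockout genotype")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (stabilization_factor <= 1) stop("stabilization_factor must be > 1")
  if (stabilized_fraction + nondecaying_fraction > 1)
    stop("stabilized_fraction + nondecaying_fraction must be <= 1")
  cfg <- list(
    n_genes = as.integer(n_genes), genotypes = genotypes,
    n_subjects_per_genotype = as.integer(n_subjects_per_genotype),
    timepoints_min = timepoints_min,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    control_halflife_range = control_halflife_range,
    fast_fraction = fast_fraction,
    slow_halflife_range = slow_halflife_range,
    stabilized_fraction = stabilized_fraction,
    stabilized_control_halflife = stabilized_control_halflife,
    stabilization_factor = stabilization_factor,
    nondecaying_fraction = nondecaying_fraction,
    nonmrna_fraction = nonmrna_fraction,
    dispersion = dispersion, library_depth = library_depth,
    renormalize_to_fixed_depth = renormalize_to_fixed_depth,
    seed = as.integer(seed))
  class(cfg) <- "decay_sim_config"
  cfg
}

#' Simulate a two-genotype actinomycin-D chase experiment with known truth
#'
#' Expected abundance follows `a_g(t) = a_g(0) * exp(-k_g * t)` per genotype.
#' Counts are drawn negative-binomial around the expected abundance scaled so
#' the expected t = 0 library total equals `library_depth`; later libraries
#' therefore shrink as the pool decays unless `renormalize_to_fixed_depth`
#' rescales every column back to the fixed depth (the source of the
#' apparent-increase artifact for slow transcripts).
#'
#' @param config a [decay_sim_config()].
#' @return a list with elements `experiment` (a [chase_experiment()]) and
#'   `truth` (a data frame with one row per gene x genotype: `gene_id`,
#'   `genotype`, `k_per_min`, `halflife_min`, `baseline`, `stabilized`, plus
#'   a gene-level `biotype`).
#' @export
simulate_chase <- function(config) {
  stopifnot(inherits(config, "decay_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))

  n_nonmrna <- round(config$nonmrna_fraction * n)
  biotype <- rep("protein_coding", n)
  if (n_nonmrna > 0)
    biotype[seq_len(n_nonmrna)] <-
      rep_len(c("rRNA", "snoRNA", "miRNA", "lincRNA"), n_nonmrna)

  mrna_idx <- which(biotype == "protein_coding")
  n_nondec <- round(config$nondecaying_fraction * n)
  n_stab <- round(config$stabilized_fraction * n)
  pool <- sample(mrna_idx)
  nondecaying <- pool[seq_len(min(n_nondec, length(pool)))]
  pool <- setdiff(pool, nondecaying)
  n_fast <- round(config$fast_fraction * length(mrna_idx))
  fast <- pool[seq_len(min(n_fast, length(pool)))]
  stabilized_idx <- sort(fast[seq_len(min(n_stab, length(fast)))])

  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  hl_ctrl <- exp(stats::runif(n, log(config$slow_halflife_range[1]),
                              log(config$slow_halflife_range[2])))
  hl_ctrl[fast] <- exp(stats::runif(length(fast),
                                    log(config$control_halflife_range[1]),
                                    log(config$control_halflife_range[2])))
  if (!is.null(config$stabilized_control_halflife))
    hl_ctrl[stabilized_idx] <- config$stabilized_control_halflife
  hl_ctrl[nondecaying] <- Inf

  genos <- config$genotypes
  halflife <- matrix(hl_ctrl, nrow = n, ncol = length(genos),
                     dimnames = list(gene_id, genos))
  for (g in genos[-1])
    halflife[stabilized_idx, g] <- hl_ctrl[stabilized_idx] * config$stabilization_factor
  k <- log(2) / halflife # Inf half-life -> k = 0

  times <- config$timepoints_min
  n_sub <- config$n_subjects_per_genotype
  scale <- config$library_depth / sum(baseline)

  samp <- expand.grid(time_min = times, subject = seq_len(n_sub),
                      genotype = genos, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  samp <- samp[, c("genotype", "subject", "time_min")]
  samp$subject <- paste0(samp$genotype, "_m", samp$subject)
  samp$sample_id <- sprintf("%s_t%03d", samp$subject, samp$time_min)
  samp <- samp[, c("sample_id", "genotype", "subject", "time_min")]

  counts <- matrix(0, nrow = n, ncol = nrow(samp),
                   dimnames = list(gene_id, samp$sample_id))
  for (j in seq_len(nrow(samp))) {
    mu <- baseline * exp(-k[, samp$genotype[j]] * samp$time_min[j]) * scale
    if (config$dispersion > 0) {
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    } else {
      counts[, j] <- mu
    }
  }
  if (config$renormalize_to_fixed_depth) {
    cs <- colSums(counts)
    counts <- sweep(counts, 2, config$library_depth / cs, `*`)
    if (config$dispersion > 0) counts <- round(counts)
  }

  ann <- data.frame(gene_id = gene_id,
                    symbol = toupper(gene_id),
                    biotype = biotype,
                    length_bp = as.integer(round(stats::rlnorm(n, log(2000), 0.5))),
                    stringsAsFactors = FALSE)
  ann$length_bp <- pmax(ann$length_bp, 100L)

  truth <- do.call(rbind, lapply(genos, function(g) data.frame(
    gene_id = gene_id, genotype = g,
    k_per_min = k[, g], halflife_min = halflife[, g],
    baseline = baseline,
    stabilized = seq_len(n) %in% stabilized_idx & g != genos[1],
    biotype = biotype, row.names = NULL, stringsAsFactors = FALSE)))
  truth$stabilized_gene <- truth$gene_id %in% gene_id[stabilized_idx]

  list(experiment = chase_experiment(counts, ann, samp), truth = truth)
}

#' Simulate 3'-UTR sequences with planted AU-rich binding sites
#'
#' Draws background sequence i.i.d. from `background_composition` and
#' overwrites it with motif occurrences at non-overlapping positions, so that
#' rescanning each sequence is guaranteed to recover every planted site.
#'
#' @param gene_ids character vector of sequence names.
#' @param site_prob probability that a gene receives at least one planted
#'   site; recycled or named per gene.
#' @param max_sites maximum number of sites planted per gene with a site.
#' @param background_composition named base frequencies over A, C, G, U.
#' @param utr_length_range integer range of drawn UTR lengths (nt).
#' @param classes motif classes to plant, as from [ttp_motif_classes()].
#' @param seed integer seed.
#' @return list with `sequences` (named character, RNA alphabet) and
#'   `planted` (data frame: `gene_id`, `motif_class`, `pattern`, `start`,
#'   `end`, 1-based inclusive).
#' @export
simulate_utrs <- function(gene_ids,
                          site_prob = 0.4,
                          max_sites = 3L,
                          background_composition = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3),
                          utr_length_range = c(100L, 400L),
                          classes = ttp_motif_classes(),
                          seed = 1L) {
  stopifnot(length(gene_ids) > 0, !anyDuplicated(gene_ids))
  if (utr_length_range[1] < max(nchar(classes$pattern)))
    stop("utr too short for requested motif")
  set.seed(seed)
  p_site <- rep_len(site_prob, length(gene_ids))
  if (!is.null(names(site_prob))) p_site <- site_prob[gene_ids]
  bases <- names(background_composition)
  seqs <- character(length(gene_ids))
  planted <- vector("list", length(gene_ids))
  for (i in seq_along(gene_ids)) {
    len <- sample(utr_length_range[1]:utr_length_range[2], 1L)
    s <- sample(bases, len, replace = TRUE, prob = background_composition)
    rows <- NULL
    if (stats::runif(1) < p_site[i]) {
      n_sites <- sample.int(max_sites, 1L)
      occupied <- rep(FALSE, len)
      for (k in seq_len(n_sites)) {
        ci <- sample.int(nrow(classes), 1L)
        pat <- strsplit(classes$pattern[ci], "")[[1]]
        w <- length(pat)
        # rejection-sample a start that does not overlap previous plants
        for (try in 1:50) {
          st <- sample.int(len - w + 1L, 1L)
          if (!any(occupied[st:(st + w - 1L)])) {
            s[st:(st + w - 1L)] <- pat
            occupied[st:(st + w - 1L)] <- TRUE
            rows <- rbind(rows, data.frame(
              gene_id = gene_ids[i], motif_class = classes$class[ci],
              pattern = classes$pattern[ci], start = st, end = st + w - 1L,
              stringsAsFactors = FALSE))
            break
          }
        }
      }
    }
    seqs[i] <- paste(s, collapse = "")
    planted[[i]] <- rows
  }
  names(seqs) <- gene_ids
  planted <- do.call(rbind, planted)
  if (is.null(planted))
    planted <- data.frame(gene_id = character(), motif_class = character(),
                          pattern = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  list(sequences = seqs, planted = planted)
}

#' Simulate LPS-induction time courses with known AUC
#'
#' Mean curves rise linearly from baseline to `baseline * peak_fold` at
#' `peak_time` and then relax exponentially back toward baseline at rate
#' `decay_to_baseline` (per hour). Replicates add multiplicative log-normal
#' noise with coefficient of variation `noise_cv`. The true AUC is the
#' composite trapezoid of the noise-free mean curve on the sampling grid.
#'
#' @param genes data frame with columns `gene_id`, `baseline`, `peak_time`,
#'   `peak_fold`, `decay_to_baseline`.
#' @param timepoints_h ordered sampling times in hours, including 0.
#' @param n_reps replicates per timepoint.
#' @param noise_cv multiplicative coefficient of variation.
#' @param seed integer seed.
#' @return list with `curves` (data frame: `gene_id`, `time`, `mean`, `sd`,
#'   `n`) and `truth` (data frame: `gene_id`, `auc`, `peak_time`,
#'   `peak_fold`).
#' @export
simulate_induction <- function(genes, timepoints_h = c(0, 0.5, 0.75, 1, 2, 4, 8, 24),
                               n_reps = 4L, noise_cv = 0.1, seed = 1L) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "baseline", "peak_time", "peak_fold",
                  "decay_to_baseline") %in% names(genes)))
  if (timepoints_h[1] != 0 || any(diff(timepoints_h) <= 0))
    stop("timepoints_h must be strictly increasing and include 0")
  if (any(genes$peak_time < min(timepoints_h) | genes$peak_time > max(timepoints_h)))
    stop("peak_time outside grid span")
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- vector("list", nrow(genes))
  truth <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    peak_val <- g$baseline * g$peak_fold
    m <- ifelse(timepoints_h <= g$peak_time,
                g$baseline + (peak_val - g$baseline) *
                  (if (g$peak_time > 0) timepoints_h / g$peak_time else 1),
                g$baseline + (peak_val - g$baseline) *
                  exp(-g$decay_to_baseline * (timepoints_h - g$peak_time)))
    reps <- matrix(m, nrow = length(m), ncol = n_reps) *
      matrix(stats::rlnorm(length(m) * n_reps, -sdlog^2 / 2, sdlog),
             nrow = length(m))
    out[[i]] <- data.frame(
      gene_id = g$gene_id, time = timepoints_h,
      mean = rowMeans(reps), sd = apply(reps, 1, stats::sd), n = n_reps,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      gene_id = g$gene_id,
      auc = trapezoid(timepoints_h, m),
      peak_time = timepoints_h[which.max(m)],
      peak_fold = max(m) / m[1], stringsAsFactors = FALSE)
  }
  list(curves = do.call(rbind, out), truth = do.call(rbind, truth))
}
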