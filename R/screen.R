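#' Configuration of the two-stage stabilization screen
#'
#' Stage 1 selects genes whose percent-remaining values are significantly
#' higher in the knockout than in the control at `stage1_window` consecutive
#' post-anchor timepoints by unpaired two-tailed t tests with a fixed
#' Bonferroni-style cutoff `stage1_alpha`. Stage 2 gates the survivors on a
#' mixed-design repeated-measures two-way ANOVA (between-subject genotype,
#' within-subject time) with Greenhouse-Geisser correction, at `stage2_alpha`
#' on `stage2_gate_term`.
#'
#' @param stage1_alpha per-timepoint p cutoff (default 0.008, i.e. roughly
#'   0.05 spread over the post-anchor tests; raw p-values are always reported
#'   so any cutoff can be re-applied).
#' @param stage1_window number of consecutive significant timepoints required
#'   (default 3).
#' @param stage1_test_variant `"equal"` (pooled-variance t, default) or
#'   `"welch"`.
#' @param require_direction require knockout mean above control mean at every
#'   qualifying timepoint (default `TRUE`: the screen is for stabilized, not
#'   merely different, transcripts).
#' @param stage2_alpha ANOVA gate (default 0.05).
#' @param stage2_gate_term `"interaction"` (genotype x time, default: a
#'   stabilization with a shared 100 percent anchor is an interaction by
#'   construction) or `"genotype"`. Both term p-values are always reported.
#' @param rank_times timepoints (minutes) averaged for the ranking metric
#'   (default 60 and 120).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(stage1_alpha = 0.008, stage1_window = 3L,
                          stage1_test_variant = c("equal", "welch"),
                          require_direction = TRUE,
                          stage2_alpha = 0.05,
                          stage2_gate_term = c("interaction", "genotype"),
                          rank_times = c(60, 120)) {
  stopifnot(stage1_alpha > 0, stage1_alpha < 1,
            stage2_alpha > 0, stage2_alpha < 1, stage1_window >= 1)
  structure(list(stage1_alpha = stage1_alpha,
                 stage1_window = as.integer(stage1_window),
                 stage1_test_variant = match.arg(stage1_test_variant),
                 require_direction = require_direction,
                 stage2_alpha = stage2_alpha,
                 stage2_gate_term = match.arg(stage2_gate_term),
                 rank_times = rank_times),
            class = "screen_config")
}

# Row-wise two-sample two-tailed t tests (X, Y: genes x subjects).
# Returns t, p, df and the group means; rows with < 2 observations in either
# group get NA.
row_t_test <- function(X, Y, var_equal = TRUE) {
  nx <- rowSums(!is.na(X)); ny <- rowSums(!is.na(Y))
  mx <- rowMeans(X, na.rm = TRUE); my <- rowMeans(Y, na.rm = TRUE)
  vx <- rowSums((X - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((Y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (my - mx) / se
  p <- 2 * stats::pt(-abs(t), df)
  bad <- nx < 2 | ny < 2
  t[bad] <- p[bad] <- df[bad] <- NA_real_
  list(t = t, p = p, df = df, mean_x = mx, mean_y = my)
}

#' Stage-1 consecutive-timepoint t-test screen
#'
#' For every post-anchor timepoint, an unpaired two-tailed t test compares
#' per-subject percent-remaining values between the two genotypes. A gene
#' passes when some run of `stage1_window` consecutive timepoints all have
#' p < `stage1_alpha` (and, if required, knockout mean above control mean).
#' The anchor timepoint is excluded: it is identically 100 in both groups.
#'
#' @param curves a `percent_remaining_curves` object.
#' @param pair character vector `c(control_label, ko_label)`.
#' @param config a [screen_config()].
#' @param genes optional subset of gene identifiers.
#' @return list of class `stage1_result`: per-gene data frame (`gene_id`,
#'   `stage1_pass`, `window_start_min`, `skipped`), and gene x timepoint
#'   matrices `t`, `p`, `diff` (knockout minus control means).
#' @export
stage1_screen <- function(curves, pair, config = screen_config(), genes = NULL) {
  stopifnot(length(pair) == 2, all(pair %in% curves$genotypes))
  if (is.null(genes)) genes <- rownames(curves$percent)
  times <- curves$timepoints[curves$timepoints > 0]
  tmat <- pmat <- dmat <- matrix(
    NA_real_, length(genes), length(times), dimnames = list(genes, times))
  for (j in seq_along(times)) {
    Xc <- subject_percents(curves, pair[1], times[j])[genes, , drop = FALSE]
    Xk <- subject_percents(curves, pair[2], times[j])[genes, , drop = FALSE]
    tt <- row_t_test(Xc, Xk, var_equal = config$stage1_test_variant == "equal")
    tmat[, j] <- tt$t; pmat[, j] <- tt$p
    dmat[, j] <- tt$mean_y - tt$mean_x
  }
  ok <- pmat < config$stage1_alpha
  if (config$require_direction) ok <- ok & dmat > 0
  ok[is.na(ok)] <- FALSE
  w <- config$stage1_window
  n_t <- length(times)
  pass <- rep(FALSE, length(genes))
  win_start <- rep(NA_real_, length(genes))
  if (n_t >= w) {
    for (j in seq_len(n_t - w + 1)) {
      run <- rowSums(ok[, j:(j + w - 1), drop = FALSE]) == w
      newly <- run & !pass
      win_start[newly] <- times[j]
      pass <- pass | run
    }
  }
  skipped <- rowSums(is.na(pmat)) == n_t
  res <- data.frame(gene_id = genes, stage1_pass = pass,
                    window_start_min = win_start,
                    skipped = ifelse(skipped, "fewer_than_2_subjects", ""),
                    stringsAsFactors = FALSE)
  structure(list(result = res, t = tmat, p = pmat, diff = dmat,
                 times = times, pair = pair),
            class = "stage1_result")
}

# Orthonormal within-subject contrast matrix ((k-1) x k).
ortho_contrasts <- function(k) {
  C <- t(stats::contr.helmert(k))
  C / sqrt(rowSums(C^2))
}

#' Mixed-design two-way repeated-measures ANOVA with Greenhouse-Geisser
#' correction
#'
#' Between-subject factor group, within-subject factor time, subjects nested
#' in group. The Greenhouse-Geisser epsilon is computed from the pooled
#' within-group covariance of the time levels and scales the degrees of
#' freedom of the within-subject terms (time, interaction). With a single
#' time level the within terms are absent and the group F is the one-way
#' between-subject ANOVA F.
#'
#' @param Y subjects x time-levels numeric matrix (complete cases).
#' @param group factor/character of length `nrow(Y)` with exactly two or more
#'   levels, each with at least 2 subjects.
#' @return list: `F_group`, `p_group`, `F_time`, `p_time`, `p_time_gg`,
#'   `F_interaction`, `p_interaction`, `p_interaction_gg`, `epsilon`,
#'   degrees of freedom.
#' @export
rm_anova_gg <- function(Y, group) {
  Y <- as.matrix(Y)
  group <- as.character(group)
  k <- ncol(Y)
  N <- nrow(Y)
  levs <- unique(group)
  a <- length(levs)
  n_i <- as.vector(table(factor(group, levels = levs)))
  if (any(n_i < 2)) stop("fewer than 2 complete subjects in a group")
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  group_means <- tapply(subj_means, factor(group, levels = levs), mean)
  ss_between <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_i * (group_means - grand)^2)
  ss_subj <- ss_between - ss_group
  df_group <- a - 1
  df_subj <- N - a
  F_group <- (ss_group / df_group) / (ss_subj / df_subj)
  p_group <- stats::pf(F_group, df_group, df_subj, lower.tail = FALSE)
  out <- list(F_group = F_group, p_group = p_group,
              df_group = c(df_group, df_subj),
              F_time = NA_real_, p_time = NA_real_, p_time_gg = NA_real_,
              F_interaction = NA_real_, p_interaction = NA_real_,
              p_interaction_gg = NA_real_, epsilon = NA_real_,
              df_time = c(NA_real_, NA_real_), n_subjects = N, k = k)
  if (k < 2) return(out)

  time_means <- colMeans(Y)
  cell_means <- apply(Y, 2, function(col)
    tapply(col, factor(group, levels = levs), mean)) # a x k
  ss_time <- N * sum((time_means - grand)^2)
  ss_int <- sum(n_i * (cell_means - outer(group_means, rep(1, k)) -
                         outer(rep(1, a), time_means) + grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_err <- ss_total - ss_between - ss_time - ss_int
  df_time <- k - 1
  df_int <- (a - 1) * (k - 1)
  df_err <- (N - a) * (k - 1)
  F_time <- (ss_time / df_time) / (ss_err / df_err)
  F_int <- (ss_int / df_int) / (ss_err / df_err)

  # pooled within-group covariance of the time levels
  S <- matrix(0, k, k)
  for (g in levs) {
    Yg <- Y[group == g, , drop = FALSE]
    S <- S + (nrow(Yg) - 1) * stats::cov(Yg)
  }
  S <- S / (N - a)
  C <- ortho_contrasts(k)
  A <- C %*% S %*% t(C)
  denom <- (k - 1) * sum(A^2)
  eps <- if (denom > 0) sum(diag(A))^2 / denom else 1
  eps <- min(max(eps, 1 / (k - 1)), 1)

  out$F_time <- F_time
  out$p_time <- stats::pf(F_time, df_time, df_err, lower.tail = FALSE)
  out$p_time_gg <- stats::pf(F_time, eps * df_time, eps * df_err, lower.tail = FALSE)
  out$F_interaction <- F_int
  out$p_interaction <- stats::pf(F_int, df_int, df_err, lower.tail = FALSE)
  out$p_interaction_gg <- stats::pf(F_int, eps * df_int, eps * df_err,
                                    lower.tail = FALSE)
  out$epsilon <- eps
  out$df_time <- c(df_time, df_err)
  out
}

#' Stage-2 repeated-measures ANOVA over whole decay curves
#'
#' For each gene, subjects with a complete percent-remaining curve (all
#' timepoints, anchor included by default) enter a mixed-design two-way ANOVA
#' ([rm_anova_gg()]); subjects with missing timepoints are dropped for that
#' gene. Per-timepoint genotype comparisons are Sidak-adjusted:
#' `p_adj = 1 - (1 - p)^m` over the m post-anchor timepoints. The stage-2
#' gate applies `stage2_alpha` to the Greenhouse-Geisser-corrected p of the
#' configured term.
#'
#' @inheritParams stage1_screen
#' @param include_t0 include the anchor timepoint as a within-subject level
#'   (default `TRUE`).
#' @return data frame: per gene the ANOVA term F and p values (uncorrected
#'   and epsilon-corrected), `gg_epsilon`, `min_sidak_p`, `n_subjects_used`,
#'   `stage2_pass`.
#' @export
stage2_rm_anova <- function(curves, pair, config = screen_config(),
                            genes = NULL, include_t0 = TRUE) {
  stopifnot(length(pair) == 2, all(pair %in% curves$genotypes))
  if (is.null(genes)) genes <- rownames(curves$percent)
  times <- curves$timepoints
  if (!include_t0) times <- times[times > 0]
  s <- curves$samples
  s <- s[s$genotype %in% pair & s$time_min %in% times, ]
  subj <- unique(s[, c("subject", "genotype")])
  # subject x time sample-id map (complete designs only)
  sample_map <- matrix(NA_character_, nrow(subj), length(times),
                       dimnames = list(subj$subject, times))
  for (i in seq_len(nrow(s)))
    sample_map[s$subject[i], as.character(s$time_min[i])] <- s$sample_id[i]

  post_times <- curves$timepoints[curves$timepoints > 0]
  m <- length(post_times)

  res <- lapply(genes, function(g) {
    vals <- curves$percent[g, , drop = TRUE]
    Y <- matrix(vals[sample_map], nrow(subj), length(times))
    complete <- stats::complete.cases(Y) & !is.na(sample_map[, 1])
    Yc <- Y[complete, , drop = FALSE]
    grp <- subj$genotype[complete]
    if (sum(grp == pair[1]) < 2 || sum(grp == pair[2]) < 2)
      return(data.frame(gene_id = g, F_genotype = NA_real_, p_genotype = NA_real_,
                        F_time = NA_real_, p_time = NA_real_, p_time_gg = NA_real_,
                        F_interaction = NA_real_, p_interaction = NA_real_,
                        p_interaction_gg = NA_real_, gg_epsilon = NA_real_,
                        min_sidak_p = NA_real_, n_subjects_used = sum(complete),
                        stage2_pass = FALSE, stringsAsFactors = FALSE))
    an <- rm_anova_gg(Yc, grp)
    # Sidak-adjusted per-timepoint comparisons on the post-anchor grid
    sidak <- vapply(post_times, function(tt) {
      Xc <- subject_percents(curves, pair[1], tt)[g, , drop = FALSE]
      Xk <- subject_percents(curves, pair[2], tt)[g, , drop = FALSE]
      p <- row_t_test(Xc, Xk, var_equal = config$stage1_test_variant == "equal")$p
      1 - (1 - p)^m
    }, numeric(1))
    gate_p <- switch(config$stage2_gate_term,
                     interaction = an$p_interaction_gg,
                     genotype = an$p_genotype)
    data.frame(gene_id = g,
               F_genotype = an$F_group, p_genotype = an$p_group,
               F_time = an$F_time, p_time = an$p_time, p_time_gg = an$p_time_gg,
               F_interaction = an$F_interaction,
               p_interaction = an$p_interaction,
               p_interaction_gg = an$p_interaction_gg,
               gg_epsilon = an$epsilon,
               min_sidak_p = if (all(is.na(sidak))) NA_real_ else min(sidak, na.rm = TRUE),
               n_subjects_used = nrow(Yc),
               stage2_pass = !is.na(gate_p) && gate_p < config$stage2_alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Half-life from a mean percent-remaining curve
#'
#' Locates the first downward crossing of 50 percent by linear interpolation
#' between the bracketing timepoints (on the percent scale by default, on the
#' log-percent scale with `log_scale = TRUE`). Curves that never drop below
#' 50 within the grid are right-censored at the grid maximum, matching the
#' "greater than 120 min" reporting convention.
#'
#' @param times timepoints in minutes, starting at 0.
#' @param percents mean percent remaining at `times` (100 at t = 0).
#' @param log_scale interpolate on log(percent) instead.
#' @return list with `halflife` (minutes) and `censored` (logical).
#' @export
estimate_half_life <- function(times, percents, log_scale = FALSE) {
  keep <- !is.na(percents)
  times <- times[keep]; percents <- percents[keep]
  if (!length(times)) stop("empty curve")
  below <- which(percents <= 50)
  below <- below[below > 1 | percents[1] <= 50]
  if (!length(below))
    return(list(halflife = max(times), censored = TRUE))
  i <- below[1]
  if (percents[i] == 50 || i == 1)
    return(list(halflife = times[i], censored = FALSE))
  p0 <- percents[i - 1]; p1 <- percents[i]
  if (log_scale) {
    f <- (log(p0) - log(50)) / (log(p0) - log(p1))
  } else {
    f <- (p0 - 50) / (p0 - p1)
  }
  list(halflife = times[i - 1] + f * (times[i] - times[i - 1]),
       censored = FALSE)
}

half_life_label <- function(hl) {
  if (hl$censored) paste0(">", format(hl$halflife)) else
    format(round(hl$halflife, 2))
}

#' Rank stabilized transcripts
#'
#' Descending by `rank_metric` (the mean knockout-minus-control difference in
#' average percent remaining at the rank timepoints, by default 60 and 120
#' min); ties broken lexicographically by gene identifier.
#'
#' @param table screen table (from [run_screen()]`$table`) or any data frame
#'   with `gene_id`, `rank_metric`, `stabilized` columns.
#' @return the stabilized rows, ordered.
#' @export
rank_stabilized <- function(table) {
  stopifnot(all(c("gene_id", "rank_metric", "stabilized") %in% names(table)))
  out <- table[table$stabilized %in% TRUE, , drop = FALSE]
  out[order(-out$rank_metric, out$gene_id), , drop = FALSE]
}

#' Run the full stabilization screen on a chase experiment
#'
#' Orchestrates normalization (median-of-ratios size factors by default,
#' total-count by flag), per-kilobase expression, per-subject
#' percent-remaining curves, the filter cascade, the stage-1
#' consecutive-timepoint t-test screen, the stage-2 repeated-measures ANOVA
#' on stage-1 survivors, ranking, and per-genotype half-life estimation.
#' Fully deterministic; every excluded or skipped gene carries a
#' machine-readable reason.
#'
#' @param experiment a [chase_experiment()].
#' @param pair `c(control_label, ko_label)`; defaults to the first two
#'   genotypes of the sample sheet.
#' @param config a [screen_config()].
#' @param normalization `"median_of_ratios"` (default) or `"total_count"`.
#' @param site_annotation optional result of [annotate_gene_set()] used to
#'   fill the binding-site flag.
#' @param known_targets optional character vector of known-target identifiers
#'   or symbols.
#' @param ... passed to [apply_filters()] (`excluded_genes`, `min_fpkm`,
#'   `decay_ceiling`, `ceiling_time`, `mrna_biotypes`).
#' @return list of class `screen_result`: `table` (one row per retained
#'   gene), `filter_report`, `curves`, `stage1`, `stage2`, `config`, `pair`.
#' @export
run_screen <- function(experiment, pair = NULL, config = screen_config(),
                       normalization = c("median_of_ratios", "total_count"),
                       site_annotation = NULL, known_targets = NULL, ...) {
  stopifnot(inherits(experiment, "chase_experiment"))
  normalization <- match.arg(normalization)
  counts <- experiment$counts
  ann <- experiment$gene_annotation
  samples <- experiment$sample_sheet
  if (is.null(pair)) pair <- unique(samples$genotype)[1:2]

  sf <- if (normalization == "median_of_ratios") size_factors(counts) else {
    cs <- colSums(counts); cs / exp(mean(log(cs)))
  }
  lengths <- stats::setNames(ann$length_bp, ann$gene_id)
  norm <- normalized_per_kb(counts, lengths, sf)
  fpkm_mat <- fpkm(counts, lengths)
  curves <- percent_remaining(norm, samples)
  filt <- apply_filters(curves, fpkm_mat, ann, control_genotype = pair[1], ...)
  retained <- filt$gene_id[filt$retained]

  s1 <- stage1_screen(curves, pair, config, genes = retained)
  passers <- s1$result$gene_id[s1$result$stage1_pass]
  s2 <- if (length(passers))
    stage2_rm_anova(curves, pair, config, genes = passers) else NULL

  times <- curves$timepoints
  post <- times[times > 0]
  mc <- curves$mean[[pair[1]]][retained, , drop = FALSE]
  mk <- curves$mean[[pair[2]]][retained, , drop = FALSE]
  sc <- curves$sd[[pair[1]]][retained, , drop = FALSE]
  sk <- curves$sd[[pair[2]]][retained, , drop = FALSE]

  rank_cols <- as.character(config$rank_times)
  if (!all(rank_cols %in% colnames(mc))) stop("rank_times absent from grid")
  rank_metric <- rowMeans(mk[, rank_cols, drop = FALSE] -
                            mc[, rank_cols, drop = FALSE])

  hl <- function(mm) vapply(retained, function(g)
    half_life_label(estimate_half_life(times, mm[g, ])), character(1))

  tab <- data.frame(gene_id = retained,
                    symbol = ann$symbol[match(retained, ann$gene_id)],
                    stringsAsFactors = FALSE)
  tab$has_ttp_site <- if (!is.null(site_annotation))
    vapply(retained, function(g) {
      a <- site_annotation[[g]]
      !is.null(a) && a$has_site
    }, logical(1)) else NA
  tab$known_target <- if (!is.null(known_targets))
    tolower(tab$gene_id) %in% tolower(known_targets) |
      tolower(tab$symbol) %in% tolower(known_targets) else NA
  colnames(mc) <- paste0("ctrl_mean_t", times)
  colnames(sc) <- paste0("ctrl_sd_t", times)
  colnames(mk) <- paste0("ko_mean_t", times)
  colnames(sk) <- paste0("ko_sd_t", times)
  pmat <- s1$p[retained, , drop = FALSE]
  colnames(pmat) <- paste0("t_test_p_t", post)
  tab <- cbind(tab, mc, sc, mk, sk, pmat)
  tab$stage1_pass <- s1$result$stage1_pass
  tab$window_start_min <- s1$result$window_start_min
  s2cols <- c("F_genotype", "p_genotype", "F_time", "p_time", "p_time_gg",
              "F_interaction", "p_interaction", "p_interaction_gg",
              "gg_epsilon", "min_sidak_p", "n_subjects_used", "stage2_pass")
  for (col in s2cols)
    tab[[col]] <- if (!is.null(s2)) s2[[col]][match(retained, s2$gene_id)] else
      rep(NA, length(retained))
  tab$stage2_pass[is.na(tab$stage2_pass)] <- FALSE
  tab$rank_metric <- rank_metric
  tab$half_life_control <- hl(curves$mean[[pair[1]]])
  tab$half_life_ko <- hl(curves$mean[[pair[2]]])
  tab$stabilized <- tab$stage1_pass & tab$stage2_pass
  tab <- tab[order(-tab$stabilized, -tab$rank_metric, tab$gene_id), ]
  rownames(tab) <- NULL

  structure(list(table = tab, filter_report = filt, curves = curves,
                 stage1 = s1, stage2 = s2, config = config, pair = pair,
                 size_factors = sf),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", nrow(x$filter_report), "genes,",
      sum(x$filter_report$retained), "retained,",
      sum(x$table$stage1_pass), "stage-1 passers,",
      sum(x$table$stabilized), "stabilized\n")
  invisible(x)
}
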