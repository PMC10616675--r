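test_that("simulated chase is deterministic and respects the null", {
  cfg <- decay_sim_config(n_genes = 60, seed = 7)
  a <- simulate_chase(cfg)
  b <- simulate_chase(cfg)
  expect_identical(a$experiment$counts, b$experiment$counts)
  expect_identical(a$truth, b$truth)

  # no planted effect: half-lives identical across genotypes for every gene
  cfg0 <- decay_sim_config(n_genes = 60, stabilized_fraction = 0, seed = 3)
  tr <- simulate_chase(cfg0)$truth
  hl <- split(tr$halflife_min, tr$genotype)
  expect_equal(hl$control, hl$ko)
  expect_false(any(tr$stabilized))
})

test_that("config invariants are enforced", {
  expect_error(decay_sim_config(timepoints_min = c(0, 30, 30)), "increasing")
  expect_error(decay_sim_config(timepoints_min = c(15, 30)), "start at 0")
  expect_error(decay_sim_config(n_subjects_per_genotype = 0), "subject")
  expect_error(decay_sim_config(dispersion = -1), "dispersion")
  expect_error(decay_sim_config(stabilization_factor = 1), "> 1")
  expect_error(decay_sim_config(stabilized_fraction = 0.5,
                                nondecaying_fraction = 0.6), "<= 1")
})

test_that("noise-free, unrenormalized decay matches the closed form", {
  cfg <- decay_sim_config(n_genes = 20, dispersion = 0,
                          renormalize_to_fixed_depth = FALSE,
                          nonmrna_fraction = 0, seed = 5)
  sim <- simulate_chase(cfg)
  e <- sim$experiment
  sf <- rep(1, ncol(e$counts))
  curves <- percent_remaining(e$counts, e$sample_sheet)
  tr <- sim$truth
  for (g in c("control", "ko")) {
    k <- tr$k_per_min[tr$genotype == g]
    expected <- 100 * exp(-outer(k, curves$timepoints))
    expect_equal(unname(curves$mean[[g]]), expected, tolerance = 1e-12)
  }
  # spot value: half-life 20 min gene has exactly 50 percent left at t = 20
  cfg2 <- decay_sim_config(n_genes = 5, dispersion = 0,
                           timepoints_min = c(0, 20, 40),
                           control_halflife_range = c(20, 20),
                           fast_fraction = 1, stabilized_fraction = 0,
                           nondecaying_fraction = 0, nonmrna_fraction = 0,
                           renormalize_to_fixed_depth = FALSE, seed = 2)
  sim2 <- simulate_chase(cfg2)
  cv <- percent_remaining(sim2$experiment$counts, sim2$experiment$sample_sheet)
  expect_equal(unname(cv$mean$control[, "20"]), rep(50, 5), tolerance = 1e-12)
  expect_equal(unname(cv$mean$control[, "40"]), rep(25, 5), tolerance = 1e-12)
})

test_that("fixed-depth renormalization conserves column totals", {
  cfg <- decay_sim_config(n_genes = 100, seed = 9)
  counts <- simulate_chase(cfg)$experiment$counts
  expect_true(all(abs(colSums(counts) - cfg$library_depth) <= cfg$n_genes))
})

test_that("planted UTR sites are recovered on rescanning", {
  u <- simulate_utrs(sprintf("g%02d", 1:40), site_prob = 0.6, seed = 21)
  expect_true(all(nchar(u$sequences) >= 100))
  for (i in seq_len(nrow(u$planted))) {
    ann <- scan_sequence(u$sequences[[u$planted$gene_id[i]]])
    hit <- ann$hits[ann$hits$motif_class == u$planted$motif_class[i] &
                      ann$hits$start == u$planted$start[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$end, u$planted$end[i])
  }
  # pure G/C background with nothing planted: no hits anywhere
  gc <- simulate_utrs("g1", site_prob = 0,
                      background_composition = c(A = 0, C = .5, G = .5, U = 0),
                      seed = 4)
  expect_false(scan_sequence(gc$sequences[[1]])$has_site)
  expect_error(simulate_utrs("g1", utr_length_range = c(5L, 8L)), "too short")
})

test_that("induction simulator returns closed-form trapezoid truth", {
  genes <- data.frame(gene_id = c("a", "b"), baseline = c(5, 10),
                      peak_time = c(0.75, 1), peak_fold = c(23, 4.4),
                      decay_to_baseline = c(0.4, 0.8),
                      stringsAsFactors = FALSE)
  sim <- simulate_induction(genes, n_reps = 4, noise_cv = 0.05, seed = 8)
  expect_equal(nrow(sim$curves), 2 * 8)
  expect_true(all(sim$truth$auc > 0))
  # constant curve: flat baseline (peak_fold 1 cannot be planted via shape,
  # so check the rectangle on the truth path directly)
  flat <- data.frame(gene_id = "c", baseline = 5, peak_time = 1,
                     peak_fold = 1, decay_to_baseline = 1)
  tr <- simulate_induction(flat, timepoints_h = c(0, 6, 12, 24),
                           noise_cv = 0, seed = 1)$truth
  expect_equal(tr$auc, 24 * 5)
  expect_error(simulate_induction(transform(genes, peak_time = 30)),
               "outside grid")
})
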