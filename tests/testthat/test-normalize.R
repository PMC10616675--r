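test_that("median-of-ratios size factors match the closed form", {
  counts <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(counts)), c(1, 1))

  doubled <- counts; doubled[, 2] <- 2 * counts[, 1]
  expect_equal(unname(size_factors(doubled)), c(1 / sqrt(2), sqrt(2)))

  single <- counts[, 1, drop = FALSE]
  expect_equal(unname(size_factors(single)), 1)

  zero <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(zero), "nonzero")
})

test_that("per-kilobase normalization and FPKM follow their formulas", {
  counts <- matrix(c(100, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lengths <- c(g1 = 1000, g2 = 500)
  expect_equal(normalized_per_kb(counts, lengths, 1)["g1", 1], 100)
  expect_equal(normalized_per_kb(counts, lengths, 2)["g2", 1], 0)
  expect_equal(unname(normalized_per_kb(matrix(100, 1, 1,
                                               dimnames = list("g1", "s")),
                                        c(g1 = 500), 2)[1, 1]), 100)
  expect_error(normalized_per_kb(counts, c(g1 = 1000), 1), "length missing")

  m <- matrix(c(10, 1e6 - 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lens <- c(g1 = 1000, g2 = 1000)
  expect_equal(fpkm(m, lens)["g1", 1], 10)
  # scale invariance: doubling every count leaves FPKM unchanged
  expect_equal(fpkm(2 * m, lens), fpkm(m, lens))
})

test_that("percent remaining anchors each subject at 100 and is scale-invariant", {
  times <- c(0, 30, 60)
  arr <- array(c(100, 100, 60, 58, 25, 27), dim = c(1, 2, 3))
  cv <- curves_from_percent(list(control = arr, ko = arr), times)
  expect_equal(unname(cv$percent[1, cv$samples$time_min == 0]), rep(100, 4))
  expect_equal(unname(cv$mean$control[1, ]), c(100, 59, 26))

  # x(0)=200, x(60)=50 -> 25
  norm <- matrix(c(200, 50), 1, 2, dimnames = list("g1", c("s0", "s60")))
  samp <- data.frame(sample_id = c("s0", "s60"), genotype = "control",
                     subject = "m1", time_min = c(0, 60))
  expect_equal(unname(percent_remaining(norm, samp)$percent[1, "s60"]), 25)
  # multiplying one subject's samples by a constant changes nothing
  expect_equal(percent_remaining(norm * 7, samp)$percent,
               percent_remaining(norm, samp)$percent)
  # zero anchor yields missing values, not infinities
  norm0 <- norm; norm0[1, 1] <- 0
  expect_true(all(is.na(percent_remaining(norm0, samp)$percent[1, ])))
  # missing anchor sample is an error
  expect_error(percent_remaining(norm[, 2, drop = FALSE], samp[2, ]), "anchor")
})

test_that("filter cascade computes order-independent reasons", {
  times <- c(0, 60, 120)
  mk <- function(p120) array(rep(c(100, 70, p120), each = 4),
                             dim = c(1, 4, 3))
  # 4 genes: decaying mRNA, non-decaying, excluded symbol, non-mRNA
  arr <- array(0, dim = c(4, 4, 3))
  for (s in 1:4) arr[, s, ] <- rbind(c(100, 50, 20), c(100, 98, 95),
                                     c(100, 40, 15), c(100, 45, 18))
  cv <- curves_from_percent(list(control = arr, ko = arr), times,
                            gene_ids = c("g1", "g2", "g3", "g4"))
  fpkm_mat <- matrix(1, 4, nrow(cv$samples),
                     dimnames = list(c("g1", "g2", "g3", "g4"),
                                     cv$samples$sample_id))
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    symbol = c("Cxcl2", "Actb", "Plekhg2", "Rn45s"),
                    biotype = c("protein_coding", "protein_coding",
                                "protein_coding", "rRNA"),
                    length_bp = 1000)
  rep1 <- apply_filters(cv, fpkm_mat, ann)
  expect_true(rep1$retained[1])
  expect_equal(rep1$reasons[[2]], "non_decaying_control")
  expect_equal(rep1$reasons[[3]], "excluded_gene")
  expect_equal(rep1$reasons[[4]], "non_mrna")
  expect_false(any(rep1$retained[2:4]))

  # low expression reason from the FPKM floor at control t0
  fpkm_low <- fpkm_mat; fpkm_low[1, cv$samples$time_min == 0] <- 0.01
  rep2 <- apply_filters(cv, fpkm_low, ann)
  expect_equal(rep2$reasons[[1]], "low_expression")

  # ceiling at exactly 85 percent is "did not decrease below": excluded
  arr85 <- arr; arr85[1, , 3] <- 85
  cv85 <- curves_from_percent(list(control = arr85, ko = arr85), times,
                              gene_ids = c("g1", "g2", "g3", "g4"))
  expect_equal(apply_filters(cv85, fpkm_mat, ann)$reasons[[1]],
               "non_decaying_control")

  # off-grid ceiling time falls back to the latest earlier timepoint
  expect_message(apply_filters(cv, fpkm_mat, ann, ceiling_time = 100),
                 "using 60 min")
})
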