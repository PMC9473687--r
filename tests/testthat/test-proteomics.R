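groups4 <- c(a1 = "control", a2 = "control", b1 = "ko", b2 = "ko")

test_that("the control-median filter keeps values at the threshold", {
  ab <- matrix(c(1.0e7, 1.0e7, 5e7, 5e7,
                 1.5e7, 1.5e7, 5e7, 5e7,
                 2.0e7, 2.0e7, 5e7, 5e7), 3, 4, byrow = TRUE,
               dimnames = list(NULL, names(groups4)))
  tab <- toy_peptide_table(ab, list(1L, 2L, 3L), groups4)
  kept <- filter_low_abundance(tab, "control", 1.5e7)
  expect_equal(kept$peptides$sequence, c("PEP2", "PEP3"))
  # threshold 0 retains everything
  expect_equal(nrow(filter_low_abundance(tab, "control", 0)$abundance), 3L)
  # all-missing control medians are treated as below threshold
  ab2 <- ab; ab2[1, 1:2] <- NA
  tab2 <- toy_peptide_table(ab2, list(1L, 2L, 3L), groups4)
  expect_equal(nrow(filter_low_abundance(tab2, "control", 1)$abundance), 2L)
  expect_error(filter_low_abundance(tab, "nosuch", 1), "no samples")
})

test_that("raising the filter threshold never enlarges the retained set", {
  set.seed(5)
  for (rep in 1:10) {
    ab <- matrix(rlnorm(20 * 4, log(1.5e7), 1), 20, 4,
                 dimnames = list(NULL, names(groups4)))
    tab <- toy_peptide_table(ab, as.list(1:20), groups4)
    thresholds <- sort(runif(4, 0.5e7, 5e7))
    kept <- lapply(thresholds, function(t) {
      filter_low_abundance(tab, "control", t)$peptides$sequence
    })
    for (i in seq_len(length(kept) - 1)) {
      expect_true(all(kept[[i + 1]] %in% kept[[i]]))
    }
  }
})

test_that("covered-exon counting unions peptide exon sets", {
  ab <- matrix(1, 2, 4, dimnames = list(NULL, names(groups4)))
  tab <- toy_peptide_table(ab, list(c(1L, 2L), c(2L, 3L)), groups4)
  expect_equal(count_covered_exons(tab), 3L)
  empty <- filter_low_abundance(tab, "control", Inf)
  expect_equal(count_covered_exons(empty), 0L)
})

test_that("constitutive normalization scales each sample to unit reference mean", {
  # 1-sample toy: constitutive peptides 4 and 6, target 10 -> 10/mean(4,6) = 2
  g1 <- c(s1 = "control")
  ab <- matrix(c(10, 4, 6), 3, 1, dimnames = list(NULL, "s1"))
  tab <- toy_peptide_table(ab, list(10L, 300L, 320L), g1)
  norm <- normalize_to_constitutive(tab, c(256L, 363L))
  expect_equal(unname(norm$abundance[1, 1]), 2)
  expect_equal(mean(norm$abundance[2:3, 1]), 1)

  # idempotence: a second pass divides by 1
  norm2 <- normalize_to_constitutive(norm, c(256L, 363L))
  expect_equal(norm2$abundance, norm$abundance)

  # peptides straddling the region boundary are excluded under "all"
  tab3 <- toy_peptide_table(ab, list(10L, c(255L, 256L), 320L), g1)
  norm3 <- normalize_to_constitutive(tab3, c(256L, 363L))
  expect_equal(unname(norm3$abundance[1, 1]), 10 / 6)

  # a sample with no constitutive value is a named error
  ab4 <- ab; ab4[2:3, 1] <- NA
  tab4 <- toy_peptide_table(ab4, list(10L, 300L, 320L), g1)
  expect_error(normalize_to_constitutive(tab4, c(256L, 363L)), "s1")
})

test_that("summaries and tests are invariant to per-sample scaling", {
  set.seed(8)
  ab <- matrix(rlnorm(40 * 4, log(10), 0.5), 40, 4,
               dimnames = list(NULL, names(groups4)))
  exon_sets <- c(as.list(70:79), as.list(80:88),
                 as.list(sample(256:363, 21, replace = FALSE)))
  tab <- toy_peptide_table(ab, exon_sets, groups4)
  ab_scaled <- ab
  ab_scaled[, 2] <- ab_scaled[, 2] * 7.3
  tab_scaled <- toy_peptide_table(ab_scaled, exon_sets, groups4)

  n1 <- normalize_to_constitutive(tab)
  n2 <- normalize_to_constitutive(tab_scaled)
  expect_equal(n2$abundance, n1$abundance)
  s1 <- summarize_region(n1, c(70, 79), "control", "ko")
  s2 <- summarize_region(n2, c(70, 79), "control", "ko")
  expect_equal(s2$percent_difference, s1$percent_difference)
  c1 <- compare_region(n1, c(70, 79), "control", "ko")
  c2 <- compare_region(n2, c(70, 79), "control", "ko")
  expect_equal(c2$p_value, c1$p_value)
})

test_that("region summaries implement the median-then-mean convention", {
  # identical groups -> zero percent difference
  ab <- matrix(rep(c(2, 2, 2, 2), each = 3), 3, 4,
               dimnames = list(NULL, names(groups4)))
  tab <- toy_peptide_table(ab, list(71L, 72L, 300L), groups4)
  s <- summarize_region(tab, c(70, 79), "control", "ko")
  expect_equal(s$percent_difference, 0)
  expect_equal(s$n_a, 2L)

  # hand-computed medians and means for an asymmetric toy
  ab2 <- matrix(c(1, 3, 4, 8,    # peptide 1: medians 2 (ctrl), 6 (ko)
                  2, 4, 6, 10),  # peptide 2: medians 3 (ctrl), 8 (ko)
                2, 4, byrow = TRUE, dimnames = list(NULL, names(groups4)))
  tab2 <- toy_peptide_table(ab2, list(71L, 75L), groups4)
  s2 <- summarize_region(tab2, c(70, 79), "control", "ko")
  expect_equal(s2$mean_a, mean(c(2, 3)))
  expect_equal(s2$mean_b, mean(c(6, 8)))
  expect_equal(s2$percent_difference, 100 * (7 - 2.5) / 2.5)

  # empty reference group flagged, not an error
  ab3 <- matrix(c(NA, NA, 5, 7), 1, 4, dimnames = list(NULL, names(groups4)))
  tab3 <- toy_peptide_table(ab3, list(55L), groups4)
  s3 <- summarize_region(tab3, c(52, 69), "control", "ko")
  expect_true(s3$undefined_reference)
  expect_true(is.na(s3$percent_difference))
})

test_that("region tests match the textbook Student t on the ln scale", {
  g6 <- c(a1 = "control", a2 = "control", a3 = "control",
          b1 = "ko", b2 = "ko", b3 = "ko")
  # 3 peptides per group position: per-peptide medians are the values below
  vals_a <- c(1, 2, 3); vals_b <- c(2, 4, 6)
  ab <- cbind(matrix(rep(vals_a, 3), 3, 3),
              matrix(rep(vals_b, 3), 3, 3))
  colnames(ab) <- names(g6)
  tab <- toy_peptide_table(ab, list(71L, 73L, 78L), g6)
  res <- compare_region(tab, c(70, 79), "control", "ko",
                        n_regions_tested = 2, alpha = 0.05, paired = FALSE)
  ora <- oracle_student_t(log(vals_b), log(vals_a))
  expect_equal(res$t_statistic, ora$t, tolerance = 1e-10)
  expect_equal(res$p_value, ora$p, tolerance = 1e-10)
  expect_equal(res$alpha_adjusted, 0.025)

  # paired default: one-sample t on the per-peptide ln ratios
  vals_b2 <- c(1.8, 4.4, 6.3)
  ab_p <- cbind(matrix(rep(vals_a, 3), 3, 3),
                matrix(rep(vals_b2, 3), 3, 3))
  colnames(ab_p) <- names(g6)
  tab_p <- toy_peptide_table(ab_p, list(71L, 73L, 78L), g6)
  res_p <- compare_region(tab_p, c(70, 79), "control", "ko")
  d <- log(vals_b2) - log(vals_a)
  t_ora <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res_p$t_statistic, t_ora, tolerance = 1e-10)
  expect_equal(res_p$p_value, 2 * pt(-abs(t_ora), 2), tolerance = 1e-10)
  expect_equal(res_p$df, 2)

  # identical groups: t = 0, p = 1, not significant
  ab_eq <- cbind(ab[, 1:3], ab[, 1:3])
  colnames(ab_eq) <- names(g6)
  tab_eq <- toy_peptide_table(ab_eq, list(71L, 73L, 78L), g6)
  res_eq <- compare_region(tab_eq, c(70, 79), "control", "ko")
  expect_equal(res_eq$t_statistic, 0)
  expect_equal(res_eq$p_value, 1)
  expect_false(res_eq$significant)
})

test_that("non-positive normalized values are excluded from the ln test with a warning", {
  ab <- matrix(c(0, 0, 3, 4,
                 1, 2, 3, 4,
                 2, 3, 4, 5), 3, 4, byrow = TRUE,
               dimnames = list(NULL, names(groups4)))
  tab <- toy_peptide_table(ab, list(71L, 72L, 73L), groups4)
  expect_warning(res <- compare_region(tab, c(70, 79), "control", "ko"),
                 "non-positive")
  expect_equal(res$n_excluded_nonpositive, 1L)
})

test_that("gel band fractions sum to one and report the isoform ratio", {
  lanes <- data.frame(long_t1 = c(2, 0, 3), short_t1 = c(2, 5, 6),
                      t2 = c(0, 0, 1))
  f <- gel_isoform_fractions(lanes)
  expect_equal(f$frac_long_t1, c(0.5, 0, 0.3))
  expect_equal(f$frac_short_t1, c(0.5, 1, 0.6))
  expect_equal(f$frac_t2, c(0, 0, 0.1))
  expect_equal(f$frac_long_t1 + f$frac_short_t1 + f$frac_t2, rep(1, 3))
  expect_equal(f$long_short_ratio[3], 0.5)
  expect_error(gel_isoform_fractions(data.frame(long_t1 = 0, short_t1 = 0,
                                                t2 = 0)),
               "no band")
})
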