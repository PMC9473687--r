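#' Construct a peptide abundance table
#'
#' Container for label-free LC-MS peptide quantification: one row per
#' peptide, one abundance column per sample, plus a sample-to-group map.
#' Abundances are peak areas in arbitrary LC-MS units; missing values (`NA`)
#' mean the peptide was not quantified in that sample.
#'
#' @param peptides Data frame with at least `sequence` and `exon_set`
#'   (list column of integer exon numbers); `n_loci` defaults to 1.
#' @param abundance Numeric matrix, peptides x samples, non-negative or NA.
#' @param groups Named character vector mapping sample name -> group label.
#' @return Object of class `peptide_table`.
#' @export
peptide_table <- function(peptides, abundance, groups) {
  peptides <- as.data.frame(peptides)
  stopifnot(is.matrix(abundance), nrow(peptides) == nrow(abundance))
  if (!"n_loci" %in% names(peptides)) peptides$n_loci <- 1L
  if (is.null(colnames(abundance))) {
    colnames(abundance) <- paste0("S", seq_len(ncol(abundance)))
  }
  if (anyDuplicated(peptides$sequence)) stop("duplicate peptide sequences")
  if (any(abundance < 0, na.rm = TRUE)) stop("negative abundances")
  missing_grp <- setdiff(colnames(abundance), names(groups))
  if (length(missing_grp)) {
    stop("samples without a group label: ", paste(missing_grp, collapse = ", "))
  }
  structure(list(peptides = peptides, abundance = abundance,
                 groups = groups[colnames(abundance)]),
            class = "peptide_table")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf("peptide_table: %d peptides x %d samples (groups: %s)%s\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(unique(x$groups), collapse = ", "),
              if (isTRUE(attr(x, "normalized"))) " [normalized]" else ""))
  invisible(x)
}

# t.test wrapper defined for degenerate inputs: zero-variance groups with
# equal means give t = 0, p = 1; with different means t = +/-Inf, p = 0
safe_t_test <- function(x, y, var_equal = TRUE, paired = FALSE) {
  degenerate <- function() {
    df <- if (paired) length(x) - 1L else length(x) + length(y) - 2L
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      list(statistic = 0, parameter = df, p.value = 1)
    } else {
      list(statistic = sign(mean(x) - mean(y)) * Inf, parameter = df,
           p.value = 0)
    }
  }
  if (paired && stats::sd(x - y) == 0) return(degenerate())
  tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal, paired = paired),
                 error = function(e) {
                   if (grepl("essentially constant", conditionMessage(e))) {
                     NULL
                   } else {
                     stop(e)
                   }
                 })
  if (is.null(tt)) return(degenerate())
  list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
       p.value = tt$p.value)
}

group_cols <- function(table, group) {
  cols <- which(table$groups == group)
  if (length(cols) == 0L) stop("no samples in group '", group, "'")
  cols
}

#' Exclude peptides with low abundance in the control group
#'
#' Retains peptides whose median peak area over the control-group samples is
#' at or above `threshold` (values strictly below are excluded). Missing
#' values are dropped before the median; a peptide missing in every control
#' sample is treated as below threshold.
#'
#' @param table A `peptide_table`.
#' @param control_group Group label defining the reference samples.
#' @param threshold Peak-area cutoff (default 1.5e7 units).
#' @return The filtered `peptide_table`.
#' @export
filter_low_abundance <- function(table, control_group, threshold = 1.5e7) {
  stopifnot(inherits(table, "peptide_table"), threshold >= 0)
  cols <- group_cols(table, control_group)
  med <- apply(table$abundance[, cols, drop = FALSE], 1,
               stats::median, na.rm = TRUE)
  keep <- !is.na(med) & med >= threshold
  table$peptides <- table$peptides[keep, , drop = FALSE]
  table$abundance <- table$abundance[keep, , drop = FALSE]
  rownames(table$peptides) <- NULL
  table
}

#' Number of distinct genomic exons covered by the table's peptides
#'
#' @param table A `peptide_table`.
#' @return Integer count of distinct exon numbers in the union of the
#'   peptides' exon sets.
#' @export
count_covered_exons <- function(table) {
  stopifnot(inherits(table, "peptide_table"))
  length(unique(unlist(table$peptides$exon_set)))
}

# does a peptide's exon_set belong to [region[1], region[2]] under a policy?
in_region <- function(exon_set, region, membership = c("all", "any")) {
  membership <- match.arg(membership)
  vapply(exon_set, function(e) {
    if (length(e) == 0L) return(FALSE)
    inside <- e >= region[1] & e <= region[2]
    if (membership == "all") all(inside) else any(inside)
  }, logical(1))
}

#' Normalize peak areas to the constitutive exon region
#'
#' Divides every abundance in a sample by the mean peak area, in that sample,
#' of peptides mapping entirely within the constitutive region (titin exons
#' 256-363 by default, chosen because this region shows no evidence of
#' alternative splicing). After the call the mean normalized abundance of the
#' constitutive peptides equals 1 in every sample, which removes per-sample
#' loading and instrument-response differences.
#'
#' @param table A `peptide_table`.
#' @param constitutive_region Length-2 integer vector, inclusive exon range.
#' @param exclude_multi_locus Drop peptides with `n_loci > 1` from the
#'   normalization denominator (default `TRUE`).
#' @return The normalized `peptide_table` (attribute `normalized` set; the
#'   per-sample factors are stored in attribute `norm_factors`).
#' @export
normalize_to_constitutive <- function(table, constitutive_region = c(256L, 363L),
                                      exclude_multi_locus = TRUE) {
  stopifnot(inherits(table, "peptide_table"))
  const <- in_region(table$peptides$exon_set, constitutive_region, "all")
  if (exclude_multi_locus) const <- const & table$peptides$n_loci == 1L
  if (!any(const)) stop("no peptides map entirely within the constitutive region")
  denom <- colMeans(table$abundance[const, , drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad)) {
    stop("no constitutive peptide value in sample(s): ",
         paste(colnames(table$abundance)[bad], collapse = ", "))
  }
  table$abundance <- sweep(table$abundance, 2, denom, "/")
  attr(table, "normalized") <- TRUE
  attr(table, "norm_factors") <- denom
  table
}

# per-peptide median normalized abundance within each group's samples
region_peptide_medians <- function(table, region, group_a, group_b,
                                   membership = "all",
                                   exclude_multi_locus = TRUE) {
  member <- in_region(table$peptides$exon_set, region, membership)
  if (exclude_multi_locus) member <- member & table$peptides$n_loci == 1L
  med_for <- function(group) {
    cols <- group_cols(table, group)
    m <- table$abundance[member, cols, drop = FALSE]
    apply(m, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else stats::median(v)
    })
  }
  list(member = which(member), a = med_for(group_a), b = med_for(group_b))
}

#' Summarize a peptide exon region per group
#'
#' Implements the region-level convention: per peptide, the median normalized
#' abundance across each group's samples; per group, the mean and SD over the
#' region's peptides of those medians. The percent difference
#' `100 * (mean_b - mean_a) / mean_a` is computed on the linear normalized
#' scale. A region with no quantified peptide in the reference group is
#' returned with `percent_difference = NA` and `undefined_reference = TRUE`
#' (exon regions absent from one genotype do occur; titin exons 52-69 are not
#' detected in wild-type muscle).
#'
#' @param table A normalized `peptide_table`.
#' @param region Length-2 inclusive genomic exon range.
#' @param group_a Reference group label (denominator of the percent
#'   difference).
#' @param group_b Comparison group label.
#' @param membership `"all"` (peptide's whole exon set inside the region;
#'   default, avoids double counting across adjacent regions) or `"any"`.
#' @param exclude_multi_locus Drop peptides occurring at more than one locus.
#' @return Object of class `region_summary`: a list with the region, per-group
#'   `n`, `mean`, `sd`, and `percent_difference`.
#' @export
summarize_region <- function(table, region, group_a, group_b,
                             membership = "all", exclude_multi_locus = TRUE) {
  stopifnot(inherits(table, "peptide_table"), length(region) == 2L)
  med <- region_peptide_medians(table, region, group_a, group_b,
                                membership, exclude_multi_locus)
  a <- med$a[!is.na(med$a)]
  b <- med$b[!is.na(med$b)]
  mean_a <- if (length(a)) mean(a) else NA_real_
  mean_b <- if (length(b)) mean(b) else NA_real_
  undefined <- length(a) == 0L || !is.finite(mean_a) || mean_a <= 0
  pd <- if (undefined || length(b) == 0L) NA_real_ else {
    100 * (mean_b - mean_a) / mean_a
  }
  structure(list(
    region = as.integer(region),
    group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = length(b),
    mean_a = mean_a, mean_b = mean_b,
    sd_a = if (length(a) > 1L) stats::sd(a) else NA_real_,
    sd_b = if (length(b) > 1L) stats::sd(b) else NA_real_,
    percent_difference = pd,
    undefined_reference = undefined), class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf(
    "region %d-%d: %s mean %.4g (n=%d), %s mean %.4g (n=%d), diff %+.1f%%\n",
    x$region[1], x$region[2], x$group_a, x$mean_a, x$n_a,
    x$group_b, x$mean_b, x$n_b, x$percent_difference))
  if (!is.null(x$p_value)) {
    cat(sprintf("  t = %.4g, p = %.4g (threshold %.4g, %ssignificant)\n",
                x$t_statistic, x$p_value, x$alpha_adjusted,
                if (x$significant) "" else "not "))
  }
  invisible(x)
}

#' Test a region's group difference on the ln scale
#'
#' Extends [summarize_region()] with a Student t-test of the
#' natural-log-transformed per-peptide group medians (the ln transform makes
#' the multiplicative peak-area noise approximately normal). The same
#' peptides are quantified in both groups, so the default is the pairwise
#' comparison: a paired t-test on each peptide's ln ratio, which cancels the
#' peptide's intrinsic ionization efficiency. An unpaired two-sample test
#' (`paired = FALSE`) is available but is conservative whenever per-peptide
#' baselines vary, because the baseline spread then inflates the pooled
#' variance. Peptides, not animals, are the replication unit; treat the
#' p-values accordingly. Significance is declared at the Bonferroni-adjusted
#' threshold `alpha / n_regions_tested`.
#'
#' Non-positive normalized medians cannot be log-transformed and are excluded
#' with a warning reporting the count.
#'
#' @inheritParams summarize_region
#' @param n_regions_tested Number of regions in the comparison family
#'   (default 2, giving the adjusted threshold 0.05/2 = 0.025).
#' @param alpha Family-wise significance level.
#' @param paired Pairwise per-peptide comparison (default `TRUE`).
#' @param var_equal Classical Student t (`TRUE`, default) or Welch; unpaired
#'   test only.
#' @return A `region_summary` with `t_statistic`, `df`, `p_value`,
#'   `alpha_adjusted`, `significant`, `n_excluded_nonpositive` added.
#' @export
compare_region <- function(table, region, group_a, group_b,
                           n_regions_tested = 2L, alpha = 0.05,
                           paired = TRUE, var_equal = TRUE,
                           membership = "all", exclude_multi_locus = TRUE) {
  stopifnot(alpha > 0, alpha < 1, n_regions_tested >= 1L)
  out <- summarize_region(table, region, group_a, group_b,
                          membership, exclude_multi_locus)
  med <- region_peptide_medians(table, region, group_a, group_b,
                                membership, exclude_multi_locus)
  if (paired) {
    ok <- !is.na(med$a) & !is.na(med$b)
    a <- med$a[ok]; b <- med$b[ok]
    n_nonpos <- sum(a <= 0 | b <= 0)
    if (n_nonpos > 0L) {
      keep <- a > 0 & b > 0
      a <- a[keep]; b <- b[keep]
    }
  } else {
    a <- med$a[!is.na(med$a)]
    b <- med$b[!is.na(med$b)]
    n_nonpos <- sum(a <= 0) + sum(b <= 0)
    if (n_nonpos > 0L) {
      a <- a[a > 0]; b <- b[b > 0]
    }
  }
  if (n_nonpos > 0L) {
    warning(sprintf("%d non-positive normalized value(s) excluded from ln-scale test",
                    n_nonpos))
  }
  out$alpha_adjusted <- alpha / n_regions_tested
  out$n_excluded_nonpositive <- n_nonpos
  out$paired <- paired
  if (length(a) >= 2L && length(b) >= 2L) {
    tt <- safe_t_test(log(b), log(a), var_equal = var_equal, paired = paired)
    out$t_statistic <- tt$statistic
    out$df <- tt$parameter
    out$p_value <- tt$p.value
    out$significant <- tt$p.value < out$alpha_adjusted
  } else {
    out$t_statistic <- NA_real_
    out$df <- NA_real_
    out$p_value <- NA_real_
    out$significant <- NA
  }
  out
}

#' Titin isoform fractions from gel band densitometry
#'
#' Vertical agarose gels resolve titin into long T1 (upper band), short T1
#' (lower band) and T2 (a major degradation product); total titin is the sum
#' of all bands. Fractions of each band over the lane total sum to 1, and the
#' long:short T1 ratio summarizes the isoform shift.
#'
#' @param lanes Data frame (or matrix) with columns `long_t1`, `short_t1`,
#'   `t2`: non-negative densitometric intensities, one row per lane.
#' @return Data frame with per-lane fractions `frac_long_t1`,
#'   `frac_short_t1`, `frac_t2`, plus `total` and `long_short_ratio`
#'   (NA when short T1 is 0).
#' @export
gel_isoform_fractions <- function(lanes) {
  lanes <- as.data.frame(lanes)
  req <- c("long_t1", "short_t1", "t2")
  stopifnot(all(req %in% names(lanes)))
  m <- as.matrix(lanes[, req])
  if (any(m < 0, na.rm = TRUE)) stop("negative band intensities")
  total <- rowSums(m)
  if (any(total <= 0)) stop("lane with no band intensity")
  data.frame(
    frac_long_t1 = m[, "long_t1"] / total,
    frac_short_t1 = m[, "short_t1"] / total,
    frac_t2 = m[, "t2"] / total,
    total = total,
    long_short_ratio = ifelse(m[, "short_t1"] > 0,
                              m[, "long_t1"] / m[, "short_t1"], NA_real_))
}
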