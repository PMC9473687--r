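#' Construct a junction count table
#'
#' Per exon and sample: reads supporting the exon's two inclusion junctions
#' (upstream + downstream, summed) and reads supporting the single
#' exon-skipping junction. Counts are non-negative integers.
#'
#' @param counts Data frame with columns `exon`, `sample`,
#'   `inclusion_reads`, `skipping_reads`.
#' @param groups Named character vector mapping sample -> group label.
#' @return Object of class `junction_counts`.
#' @export
junction_counts <- function(counts, groups) {
  counts <- as.data.frame(counts)
  req <- c("exon", "sample", "inclusion_reads", "skipping_reads")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns ", paste(req, collapse = ", "))
  }
  if (any(counts$inclusion_reads < 0, na.rm = TRUE) ||
      any(counts$skipping_reads < 0, na.rm = TRUE)) {
    stop("negative junction counts")
  }
  missing_grp <- setdiff(unique(counts$sample), names(groups))
  if (length(missing_grp)) {
    stop("samples without a group label: ", paste(missing_grp, collapse = ", "))
  }
  structure(list(counts = counts, groups = groups),
            class = "junction_counts")
}

#' Percent spliced in from junction counts
#'
#' Estimates, per exon and sample, the fraction of transcripts that include
#' the exon. An included exon contributes reads to two junctions while a
#' skipped exon contributes to one, so the default estimator halves the
#' inclusion evidence: `PSI = (I/2) / (I/2 + S)`. The raw ratio `I / (I + S)`
#' is available with `method = "raw"`. PSI is undefined (`NA`, never 0) when
#' an exon has zero junction evidence in a sample.
#'
#' @param counts A `junction_counts` object.
#' @param method `"junction_normalized"` (default) or `"raw"`.
#' @return Object of class `psi_table`: list with `psi` (exon x sample
#'   matrix, values in `[0, 1]` or NA), `groups`, `method`.
#' @export
compute_psi <- function(counts, method = c("junction_normalized", "raw")) {
  stopifnot(inherits(counts, "junction_counts"))
  method <- match.arg(method)
  d <- counts$counts
  exons <- sort(unique(d$exon))
  samples <- unique(d$sample)
  psi <- matrix(NA_real_, length(exons), length(samples),
                dimnames = list(exons, samples))
  I <- d$inclusion_reads
  S <- d$skipping_reads
  val <- ifelse(I + S > 0,
                if (method == "junction_normalized") {
                  (I / 2) / (I / 2 + S)
                } else {
                  I / (I + S)
                },
                NA_real_)
  psi[cbind(match(d$exon, exons), match(d$sample, samples))] <- val
  structure(list(psi = psi, groups = counts$groups[samples], method = method),
            class = "psi_table")
}

#' @export
print.psi_table <- function(x, ...) {
  cat(sprintf("psi_table: %d exons x %d samples (%s estimator)\n",
              nrow(x$psi), ncol(x$psi), x$method))
  invisible(x)
}

#' Per-exon group difference in PSI
#'
#' `delta PSI = mean PSI(group_b) - mean PSI(group_a)` per exon, with group
#' means over samples with defined PSI. The convention here (and in the
#' knockout experiments this mirrors) is group_b = knockout, group_a =
#' control, so positive values mean more inclusion after knockout.
#'
#' @param psi A `psi_table`.
#' @param group_a,group_b Group labels.
#' @return Data frame with `exon`, `psi_a`, `psi_b`, `delta_psi` (NA when a
#'   group has no defined PSI at the exon).
#' @export
delta_psi <- function(psi, group_a, group_b) {
  stopifnot(inherits(psi, "psi_table"))
  mean_grp <- function(group) {
    cols <- which(psi$groups == group)
    if (length(cols) == 0L) stop("no samples in group '", group, "'")
    rowMeans(psi$psi[, cols, drop = FALSE], na.rm = TRUE)
  }
  a <- mean_grp(group_a)
  b <- mean_grp(group_b)
  a[is.nan(a)] <- NA_real_
  b[is.nan(b)] <- NA_real_
  data.frame(exon = as.integer(rownames(psi$psi)),
             psi_a = a, psi_b = b, delta_psi = b - a, row.names = NULL)
}

#' Aggregate exon PSI into splicing events and test group differences
#'
#' A splicing event is a contiguous exon range whose exons splice together.
#' Per sample, the event PSI is the mean over member exons with defined PSI
#' (NA if none). Each event is compared between groups with a two-sample
#' t-test across samples (samples, not exons, are the replicates; no
#' correction across events, matching per-event reporting).
#'
#' @param psi A `psi_table`.
#' @param events Named list of length-2 inclusive exon ranges; default the
#'   three proximal-Ig events 52-69, 70-79, 80-88.
#' @param group_a,group_b Group labels (difference is b - a).
#' @param var_equal Classical Student t (default) or Welch.
#' @return List with `sample_psi` (event x sample matrix) and `tests`
#'   (data frame: event, mean_a, mean_b, delta_psi, t, df, p_value).
#' @export
aggregate_events <- function(psi, events = titin_proximal_ig_events(),
                             group_a, group_b, var_equal = TRUE) {
  stopifnot(inherits(psi, "psi_table"), length(events) >= 1L)
  rng <- do.call(rbind, lapply(events, as.integer))
  o <- order(rng[, 1])
  if (any(rng[o, 1][-1] <= rng[o, 2][-nrow(rng)])) {
    stop("events overlap")
  }
  exons <- as.integer(rownames(psi$psi))
  ev_psi <- matrix(NA_real_, length(events), ncol(psi$psi),
                   dimnames = list(names(events), colnames(psi$psi)))
  for (i in seq_along(events)) {
    r <- events[[i]]
    rows <- which(exons >= r[1] & exons <= r[2])
    if (length(rows) == 0L) next
    v <- colMeans(psi$psi[rows, , drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    ev_psi[i, ] <- v
  }

  cols_a <- which(psi$groups == group_a)
  cols_b <- which(psi$groups == group_b)
  tests <- do.call(rbind, lapply(seq_along(events), function(i) {
    va <- ev_psi[i, cols_a]; va <- va[!is.na(va)]
    vb <- ev_psi[i, cols_b]; vb <- vb[!is.na(vb)]
    tt <- if (length(va) >= 2L && length(vb) >= 2L) {
      safe_t_test(vb, va, var_equal = var_equal)
    } else NULL
    data.frame(event = names(events)[i],
               start = rng[i, 1], end = rng[i, 2],
               n_a = length(va), n_b = length(vb),
               mean_a = if (length(va)) mean(va) else NA_real_,
               mean_b = if (length(vb)) mean(vb) else NA_real_,
               delta_psi = if (length(va) && length(vb)) {
                 mean(vb) - mean(va)
               } else NA_real_,
               t_statistic = if (is.null(tt)) NA_real_ else tt$statistic,
               df = if (is.null(tt)) NA_real_ else tt$parameter,
               p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  }))
  rownames(tests) <- NULL
  list(sample_psi = ev_psi, tests = tests)
}

#' Default proximal-Ig splicing events
#'
#' The large proximal-Ig splicing change spans titin exons 52-88; it is split
#' into three smaller events (52-69, 70-79, 80-88) by similarity of PSI
#' values, which stabilizes the per-event statistics.
#'
#' @return Named list of inclusive exon ranges.
#' @export
titin_proximal_ig_events <- function() {
  list("52-69" = c(52L, 69L),
       "70-79" = c(70L, 79L),
       "80-88" = c(80L, 88L))
}

#' Segment an exon range into events by PSI similarity
#'
#' Partitions a contiguous exon range into `k` contiguous segments minimizing
#' the total within-segment sum of squared deviations of the per-exon mean
#' PSI (mean over all samples with defined PSI). Solved exactly by dynamic
#' programming; ties are broken toward the earliest boundaries.
#'
#' @param psi A `psi_table`.
#' @param range Length-2 inclusive exon range.
#' @param k Number of segments (1 <= k <= number of exons in the range).
#' @return Data frame with `segment`, `start`, `end` (exon numbers) and the
#'   segment mean PSI; total cost in attribute `cost`.
#' @export
segment_event_by_similarity <- function(psi, range, k) {
  stopifnot(inherits(psi, "psi_table"), length(range) == 2L, k >= 1L)
  exons <- as.integer(rownames(psi$psi))
  rows <- which(exons >= range[1] & exons <= range[2])
  x <- rowMeans(psi$psi[rows, , drop = FALSE], na.rm = TRUE)
  if (anyNA(x) || any(is.nan(x))) {
    stop("exon(s) with no defined PSI in the range")
  }
  n <- length(x)
  if (k > n) stop("k exceeds the number of exons in the range")

  # cost[i,j] = SSE of x[i..j] via prefix sums
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) {
    s <- cs[j + 1] - cs[i]; s2 <- cs2[j + 1] - cs2[i]
    max(s2 - s^2 / (j - i + 1), 0)
  }
  # dp[m, j]: best cost of splitting x[1..j] into m segments
  dp <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) dp[1, j] <- sse(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf; best_i <- 0L
        for (i in (m - 1):(j - 1)) {  # last segment = x[(i+1)..j]
          cost <- dp[m - 1, i] + sse(i + 1, j)
          if (cost < best - 1e-12) { best <- cost; best_i <- i }
        }
        dp[m, j] <- best; cut[m, j] <- best_i
      }
    }
  }
  # backtrack
  ends <- integer(k); ends[k] <- n
  if (k > 1) for (m in k:2) ends[m - 1] <- cut[m, ends[m]]
  starts <- c(1L, ends[-k] + 1L)
  seg <- data.frame(segment = seq_len(k),
                    start = exons[rows][starts], end = exons[rows][ends],
                    mean_psi = vapply(seq_len(k), function(m) {
                      mean(x[starts[m]:ends[m]])
                    }, numeric(1)))
  attr(seg, "cost") <- dp[k, n]
  seg
}
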