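# Independent reference computations and small fixture builders used across
# the suite. Oracles are deliberately written from first principles (closed
# forms, brute-force enumeration) so they share no code with the paths they
# check.

# classical equal-variance two-sample t from the textbook formula
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# two-sided variance-ratio p from the F CDF
oracle_f_test <- function(x, y) {
  f <- var(x) / var(y)
  df1 <- length(x) - 1; df2 <- length(y) - 1
  tail <- pf(f, df1, df2)
  list(f = f, p = min(1, 2 * min(tail, 1 - tail)))
}

# exhaustive search over contiguous k-partitions of x minimizing total
# within-segment sum of squares; earliest-boundary tie-break
oracle_best_partition <- function(x, k) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- NULL; best_cost <- Inf
  cuts <- utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)
  if (k == 1) cuts <- list(integer(0))
  for (cut in cuts) {
    starts <- c(1, cut + 1); ends <- c(cut, n)
    cost <- sum(vapply(seq_len(k), function(m) sse(x[starts[m]:ends[m]]),
                       numeric(1)))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- cbind(start = starts, end = ends)
    }
  }
  list(cost = best_cost, partition = best)
}

# all (overlapping) substring match positions, by brute-force scan
oracle_find_all <- function(pattern, text) {
  L <- nchar(pattern)
  hits <- integer(0)
  for (i in seq_len(nchar(text) - L + 1)) {
    if (substring(text, i, i + L - 1) == pattern) hits <- c(hits, i)
  }
  hits
}

# random codon-aligned transcript with exon boundaries tiling it
random_transcript <- function(n_res = 60, n_exons = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  prot <- paste(sample(aas, n_res, replace = TRUE), collapse = "")
  codon_of <- vapply(aas, function(a) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  }, character(1))
  nt <- paste(codon_of[strsplit(prot, "")[[1]]], collapse = "")
  n <- nchar(nt)
  n_exons <- min(n_exons, n)
  cuts <- sort(sample(seq_len(n - 1), n_exons - 1))
  starts <- c(1L, cuts + 1L); ends <- c(cuts, n)
  list(seq = nt, protein = prot,
       boundaries = data.frame(index = seq_len(n_exons),
                               start = starts, end = ends))
}

# tiny in-memory peptide table: one synthetic peptide per row
toy_peptide_table <- function(abundance, exon_sets, groups, n_loci = NULL) {
  np <- nrow(abundance)
  peptides <- data.frame(sequence = paste0("PEP", seq_len(np)))
  peptides$exon_set <- exon_sets
  if (!is.null(n_loci)) peptides$n_loci <- n_loci
  peptide_table(peptides, abundance, groups)
}

# shared medium-size synthetic titin model (built once per test run)
shared_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_titin_model(seed = 101)
      attr(cache, "digest") <- digest_tryptic(cache, 0L)
    }
    cache
  }
})
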