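#' Ground-truth parameter record for the synthetic generators
#'
#' Bundles every parameter the generators draw from, so recovery tests can
#' read the truth from the same object the data came from. Defaults mirror
#' the knockout study conditions this package models: +18%/+16%
#' peptide-abundance effects on titin exon regions 70-79/80-88, a +0.3 PSI
#' shift across exons 52-88, sarcomere length means 2.12 (control) and 2.28
#' um (knockout) with a variance ratio of 3.62, and Z-to-N2A epitope offsets
#' of 182.4 (control) and 229.5 nm (knockout).
#'
#' @param seed Integer seed; every generator is deterministic given the
#'   truth's seed.
#' @param peptide_effects Named list: `"start-end"` exon region ->
#'   multiplicative knockout/control abundance ratio.
#' @param ln_sd SD of the ln-scale multiplicative peak-area noise.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-peptide
#'   baseline peak areas (LC-MS units).
#' @param psi_exons Integer vector of exons simulated for splicing.
#' @param psi_shift_region Exon range receiving the PSI shift.
#' @param psi_control,psi_shift Baseline PSI inside the shifted region and
#'   the knockout increment; `psi_background` elsewhere.
#' @param read_depth Junction reads per exon and sample.
#' @param sarcomere_mean_um,sarcomere_sd_um Named (`control`, `ko`) sarcomere
#'   length means and SDs in um.
#' @param epitope_offset_nm Named Z-line to N2A epitope offsets in nm.
#' @param localization_sd_nm SD of per-epitope localization jitter.
#' @param psf_sd_nm Gaussian point-spread sigma of the imaging model.
#' @param pixel_size_nm Pixel size of simulated profiles.
#' @param background_sd Additive background noise as a fraction of peak
#'   amplitude.
#' @return Object of class `simulation_truth` (a list of the above).
#' @export
simulation_truth <- function(seed = 1L,
                             peptide_effects = list("70-79" = 1.18,
                                                    "80-88" = 1.16),
                             ln_sd = 0.25,
                             baseline_meanlog = log(5e7),
                             baseline_sdlog = 0.5,
                             psi_exons = 40:100,
                             psi_shift_region = c(52L, 88L),
                             psi_control = 0.5,
                             psi_shift = 0.3,
                             psi_background = 0.95,
                             read_depth = 500L,
                             sarcomere_mean_um = c(control = 2.12, ko = 2.28),
                             sarcomere_sd_um = c(control = 0.10,
                                                 ko = 0.10 * sqrt(3.62)),
                             epitope_offset_nm = c(control = 182.4,
                                                   ko = 229.5),
                             localization_sd_nm = 10,
                             psf_sd_nm = 100,
                             pixel_size_nm = 20,
                             background_sd = 0.02) {
  stopifnot(ln_sd >= 0, all(unlist(peptide_effects) > 0),
            psi_control >= 0, psi_control + psi_shift <= 1,
            read_depth >= 0, all(sarcomere_sd_um >= 0),
            localization_sd_nm >= 0, psf_sd_nm > 0, pixel_size_nm > 0)
  structure(as.list(environment()), class = "simulation_truth")
}

parse_region_key <- function(key) {
  as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
}

#' Synthetic titin-like exon model
#'
#' Builds a transcript whose tryptic digest yields a fixed number of unique
#' 4-residue peptides (3 random residues + K) entirely within each exon, so
#' every genomic exon region used downstream has a known peptide complement.
#' This is a synthetic stand-in for the real titin transcript: it reproduces
#' the exon-to-peptide bookkeeping, not titin's sequence.
#'
#' @param n_exons Number of exons (default 363, the titin genomic count).
#' @param peptides_per_exon Unique tryptic peptides encoded per exon.
#' @param seed Integer seed.
#' @return An `exon_model` whose genomic numbers are `1:n_exons`.
#' @export
synthetic_titin_model <- function(n_exons = 363L, peptides_per_exon = 3L,
                                  seed = 1L) {
  stopifnot(n_exons >= 1L, peptides_per_exon >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  alphabet <- setdiff(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], c())  # no K/R/P
  n_pep <- n_exons * peptides_per_exon
  combos <- expand.grid(a = alphabet, b = alphabet, c = alphabet,
                        stringsAsFactors = FALSE)
  if (n_pep > nrow(combos)) stop("too many peptides for unique 4-mers")
  pick <- sample(nrow(combos), n_pep)
  pep <- paste0(combos$a[pick], combos$b[pick], combos$c[pick], "K")
  # reverse-translate with a fixed codon per residue
  codon_of <- vapply(c(alphabet, "K"), function(aa) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa][1]
  }, character(1))
  nt <- vapply(pep, function(p) {
    paste(codon_of[strsplit(p, "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  exon_seq <- vapply(seq_len(n_exons), function(e) {
    paste(nt[((e - 1L) * peptides_per_exon + 1L):(e * peptides_per_exon)],
          collapse = "")
  }, character(1))
  exon_seq[n_exons] <- paste0(exon_seq[n_exons], "TAA")
  len <- nchar(exon_seq)
  ends <- cumsum(len)
  boundaries <- data.frame(index = seq_len(n_exons),
                           start = c(1L, ends[-n_exons] + 1L), end = ends)
  build_exon_model(paste(exon_seq, collapse = ""), boundaries,
                   cds_start = 1L, transcript_id = "synthetic_titin")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a label-free LC-MS peptide table
#'
#' Per peptide and sample: `abundance = baseline * region_effect *
#' exp(N(0, ln_sd))`, with the multiplicative region effect applied to the
#' knockout group only. Baselines are log-normal per peptide and shared
#' across samples, so the noise model is purely multiplicative, matching the
#' rationale for ln-transforming peak areas before testing.
#'
#' @param model An `exon_model` (e.g. [synthetic_titin_model()]).
#' @param truth A [simulation_truth()]; its `seed` drives the draw.
#' @param n_control,n_ko Samples per group (defaults 5 and 6, the study's
#'   LC-MS animal counts).
#' @param peptides Optional precomputed `digest_tryptic(model, 0)` result,
#'   to amortize digestion across many replicates.
#' @return List with `table` (a `peptide_table`; groups `control`/`ko`) and
#'   `truth`.
#' @export
simulate_peptide_table <- function(model, truth, n_control = 5L, n_ko = 6L,
                                   peptides = NULL) {
  stopifnot(inherits(model, "exon_model"),
            inherits(truth, "simulation_truth"))
  if (is.null(peptides)) peptides <- digest_tryptic(model, 0L)
  peptides <- peptides[nchar(peptides$sequence) >= 2L, , drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  np <- nrow(peptides)
  samples <- c(paste0("ctrl_", seq_len(n_control)),
               paste0("ko_", seq_len(n_ko)))
  groups <- stats::setNames(rep(c("control", "ko"), c(n_control, n_ko)),
                            samples)
  baseline <- stats::rlnorm(np, truth$baseline_meanlog, truth$baseline_sdlog)
  effect <- rep(1, np)
  for (key in names(truth$peptide_effects)) {
    r <- parse_region_key(key)
    effect[in_region(peptides$exon_set, r, "all")] <-
      truth$peptide_effects[[key]]
  }
  noise <- matrix(exp(stats::rnorm(np * length(samples), 0, truth$ln_sd)),
                  np, length(samples))
  ab <- baseline * noise
  ko_cols <- groups == "ko"
  ab[, ko_cols] <- ab[, ko_cols] * effect
  colnames(ab) <- samples
  list(table = peptide_table(peptides, ab, groups), truth = truth)
}

#' Simulate junction count tables at known PSI
#'
#' For an exon with true inclusion fraction `psi` and read depth `D`, the
#' number of inclusion successes is `Binomial(D, psi)`; inclusion reads are
#' doubled (`I = 2 * successes`, one read per inclusion junction) and
#' skipping reads are the failures (`S = D - successes`), so the
#' junction-normalized estimator `(I/2)/(I/2 + S)` is unbiased for `psi`.
#'
#' @param truth A [simulation_truth()].
#' @param n_control,n_ko Samples per group (default 3, the RNAseq group
#'   size).
#' @return List with `counts` (a `junction_counts`) and `truth`; the true
#'   per-exon PSI per group is in `truth_psi`.
#' @export
simulate_exon_counts <- function(truth, n_control = 3L, n_ko = 3L) {
  stopifnot(inherits(truth, "simulation_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  exons <- truth$psi_exons
  in_shift <- exons >= truth$psi_shift_region[1] &
    exons <= truth$psi_shift_region[2]
  psi_ctrl <- ifelse(in_shift, truth$psi_control, truth$psi_background)
  psi_ko <- ifelse(in_shift, truth$psi_control + truth$psi_shift,
                   truth$psi_background)
  samples <- c(paste0("ctrl_", seq_len(n_control)),
               paste0("ko_", seq_len(n_ko)))
  groups <- stats::setNames(rep(c("control", "ko"), c(n_control, n_ko)),
                            samples)
  rows <- do.call(rbind, lapply(seq_along(samples), function(s) {
    p <- if (groups[s] == "ko") psi_ko else psi_ctrl
    succ <- stats::rbinom(length(exons), truth$read_depth, p)
    data.frame(exon = exons, sample = samples[s],
               inclusion_reads = 2L * succ,
               skipping_reads = truth$read_depth - succ)
  }))
  list(counts = junction_counts(rows, groups), truth = truth,
       truth_psi = data.frame(exon = exons, psi_control = psi_ctrl,
                              psi_ko = psi_ko))
}

#' Simulate multichannel sarcomere line profiles
#'
#' Places Z-lines at cumulative positions with spacings drawn from
#' `N(mean, sd)` for the requested group, renders the Z-line (`actinin`)
#' channel as a sum of Gaussians of width `psf_sd_nm`, and renders the `n2a`
#' epitope channel as Gaussians offset by `+/-(epitope_offset + jitter)`
#' around each Z-line (one epitope on each side, the doublet geometry of a
#' titin epitope flanking the Z-disc). Additive Gaussian background noise is
#' controlled by `background_sd`. With `sd = 0` and zero noise terms the
#' generator is exactly periodic.
#'
#' @param truth A [simulation_truth()].
#' @param n_sarcomeres Number of sarcomeres along the profile.
#' @param group `"control"` or `"ko"`: selects length mean/SD and epitope
#'   offset from the truth.
#' @return List with `profiles` (a `line_profile_set` with channels
#'   `actinin`, `n2a`), `truth`, and the generating `z_positions_nm` /
#'   `epitope_positions_nm`.
#' @export
simulate_line_profiles <- function(truth, n_sarcomeres = 300L,
                                   group = c("control", "ko")) {
  stopifnot(inherits(truth, "simulation_truth"), n_sarcomeres >= 1L)
  group <- match.arg(group)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(truth$seed)
  mean_nm <- truth$sarcomere_mean_um[[group]] * 1000
  sd_nm <- truth$sarcomere_sd_um[[group]] * 1000
  offset <- truth$epitope_offset_nm[[group]]

  spacing <- stats::rnorm(n_sarcomeres, mean_nm, sd_nm)
  margin <- 2000
  z <- margin + c(0, cumsum(spacing))
  jit <- function(n) stats::rnorm(n, 0, truth$localization_sd_nm)
  epi <- sort(c(z - offset - jit(length(z)), z + offset + jit(length(z))))

  L <- ceiling((max(z) + margin) / truth$pixel_size_nm)
  pos <- (seq_len(L) - 1) * truth$pixel_size_nm
  render <- function(centers) {
    y <- numeric(L)
    half <- 5 * truth$psf_sd_nm
    for (c0 in centers) {
      i0 <- max(1L, floor((c0 - half) / truth$pixel_size_nm) + 1L)
      i1 <- min(L, ceiling((c0 + half) / truth$pixel_size_nm) + 1L)
      idx <- i0:i1
      y[idx] <- y[idx] + exp(-(pos[idx] - c0)^2 / (2 * truth$psf_sd_nm^2))
    }
    if (truth$background_sd > 0) {
      y <- y + stats::rnorm(L, 0, truth$background_sd)
    }
    y
  }
  profiles <- line_profile_set(
    list(actinin = render(z), n2a = render(epi)),
    pixel_size = truth$pixel_size_nm)
  list(profiles = profiles, truth = truth, group = group,
       z_positions_nm = z, epitope_positions_nm = epi)
}
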