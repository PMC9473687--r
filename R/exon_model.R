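#' Build an exon-annotated protein model from a transcript
#'
#' Translates the coding sequence of a transcript and records, for every
#' residue, the set of exons its codon nucleotides touch. Exon boundaries are
#' 1-based inclusive transcript coordinates and must tile the transcript
#' exactly (no gaps, no overlaps). Translation starts at `cds_start` and stops
#' at the first in-frame stop codon; trailing sequence after the stop is
#' ignored. A residue whose codon spans an exon junction is annotated with
#' every exon the codon overlaps.
#'
#' Exon numbers initially equal the transcript ordinal (`index`); use
#' [renumber_exons()] to convert to a genomic numbering scheme. For mouse
#' titin the transcript carries 347 of the 363 genomic exons, so transcript
#' ordinals and genomic numbers diverge after the first skipped exon.
#'
#' @param transcript_seq Single nucleotide string (A/C/G/T; U accepted).
#' @param boundaries Data frame with columns `index`, `start`, `end`
#'   (1-based inclusive transcript coordinates), optionally `genomic_number`.
#' @param cds_start 1-based offset of the first coding nucleotide.
#' @return An object of class `exon_model`: a list with elements
#'   `transcript_id`, `exons` (data frame: `index`, `start`, `end`,
#'   `genomic_number`, `sequence`), `cds_start`, `cds_end`, `protein`
#'   (amino-acid string, stop excluded) and `residue_exons` (list, one
#'   integer vector of genomic exon numbers per residue).
#' @export
build_exon_model <- function(transcript_seq, boundaries, cds_start = 1L,
                             transcript_id = "transcript") {
  stopifnot(is.character(transcript_seq), length(transcript_seq) == 1L)
  transcript_seq <- toupper(gsub("U", "T", transcript_seq))
  n <- nchar(transcript_seq)
  b <- as.data.frame(boundaries)
  req <- c("index", "start", "end")
  if (!all(req %in% names(b))) {
    stop("boundaries must have columns index, start, end")
  }
  b <- b[order(b$index), , drop = FALSE]
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  if (any(b$end < b$start)) stop("exon with end < start")
  if (b$start[1] != 1L || b$end[nrow(b)] != n ||
      (nrow(b) > 1L && any(b$start[-1] != b$end[-nrow(b)] + 1L))) {
    stop("exon boundaries do not tile the transcript (gap or overlap)")
  }
  if (cds_start < 1L || cds_start > n - 2L) {
    stop("cds_start outside transcript or CDS shorter than one codon")
  }
  b$genomic_number <- if ("genomic_number" %in% names(b)) {
    as.integer(b$genomic_number)
  } else {
    b$index
  }
  if (anyDuplicated(stats::na.omit(b$genomic_number))) {
    stop("genomic_number must be injective")
  }
  b$sequence <- substring(transcript_seq, b$start, b$end)

  cds <- substring(transcript_seq, cds_start, n)
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")[1]
  n_res <- if (is.na(stop_at)) n_codon else stop_at - 1L
  if (n_res < 1L) stop("CDS opens with a stop codon; empty protein")
  protein <- paste(aa[seq_len(n_res)], collapse = "")
  cds_end <- cds_start - 1L +
    (if (is.na(stop_at)) 3L * n_codon else 3L * stop_at)

  # exon index of every transcript nucleotide, then per-codon unique exons
  exon_of_nt <- findInterval(seq_len(n), b$start)
  residue_exons <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    nt <- cds_start - 1L + (3L * i - 2L):(3L * i)
    residue_exons[[i]] <- sort(unique(b$genomic_number[exon_of_nt[nt]]))
  }

  structure(
    list(transcript_id = transcript_id,
         exons = b[, c("index", "start", "end", "genomic_number", "sequence")],
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         protein = protein, residue_exons = residue_exons),
    class = "exon_model")
}

#' @export
print.exon_model <- function(x, ...) {
  cat(sprintf("exon_model '%s': %d exons, protein %d aa (CDS %d..%d)\n",
              x$transcript_id, nrow(x$exons), nchar(x$protein),
              x$cds_start, x$cds_end))
  invisible(x)
}

#' Renumber transcript exons to a genomic scheme
#'
#' Converts transcript-ordinal exon numbers to genomic exon numbers, either
#' through an explicit mapping table (the primary path) or by exact sequence
#' matching against an ordered list of genomic exon sequences. Genomic exons
#' absent from the transcript simply have no preimage. No alignment
#' heuristics are applied: a transcript exon must match exactly one genomic
#' exon sequence, and a match to two or more is an ambiguity error.
#'
#' @param model An [build_exon_model()] result.
#' @param genomic_exon_seqs Character vector of genomic exon sequences in
#'   genomic order (genomic number = position in this vector).
#' @param mapping Data frame with columns `index`, `genomic_number` covering
#'   all transcript exons; takes precedence over `genomic_exon_seqs`.
#' @param allow_partial If `TRUE`, transcript exons with no exact genomic
#'   match get `NA` genomic numbers (reported via a warning) instead of an
#'   error.
#' @return The model with `genomic_number` and `residue_exons` updated.
#' @export
renumber_exons <- function(model, genomic_exon_seqs = NULL, mapping = NULL,
                           allow_partial = FALSE) {
  stopifnot(inherits(model, "exon_model"))
  ex <- model$exons
  if (!is.null(mapping)) {
    m <- as.data.frame(mapping)
    if (!all(c("index", "genomic_number") %in% names(m))) {
      stop("mapping must have columns index, genomic_number")
    }
    pos <- match(ex$index, m$index)
    if (anyNA(pos)) {
      stop("mapping does not cover transcript exon(s): ",
           paste(ex$index[is.na(pos)], collapse = ", "))
    }
    gnum <- as.integer(m$genomic_number[pos])
  } else if (!is.null(genomic_exon_seqs)) {
    gseq <- toupper(gsub("U", "T", as.character(genomic_exon_seqs)))
    gnum <- rep(NA_integer_, nrow(ex))
    for (i in seq_len(nrow(ex))) {
      hits <- which(gseq == ex$sequence[i])
      if (length(hits) > 1L) {
        stop(sprintf(
          "transcript exon %d matches %d genomic exons (%s): ambiguous",
          ex$index[i], length(hits), paste(hits, collapse = ", ")))
      }
      if (length(hits) == 1L) gnum[i] <- hits
    }
    if (anyNA(gnum)) {
      msg <- paste("transcript exon(s) with no exact genomic match:",
                   paste(ex$index[is.na(gnum)], collapse = ", "))
      if (!allow_partial) stop(msg)
      warning(msg)
    }
  } else {
    stop("supply genomic_exon_seqs or mapping")
  }
  if (anyDuplicated(stats::na.omit(gnum))) {
    stop("renumbering is not injective")
  }
  old <- ex$genomic_number
  model$exons$genomic_number <- gnum
  relabel <- function(v) sort(unique(gnum[match(v, old)]))
  model$residue_exons <- lapply(model$residue_exons, relabel)
  model
}

#' In silico tryptic digestion with exon annotation
#'
#' Cleaves the model's protein after every K or R not followed by P, then
#' enumerates peptides with up to `missed_cleavages` internal missed cleavage
#' sites. Each peptide is annotated with the union of exons touched by its
#' residues and with `n_loci`, the number of distinct occurrences of its
#' sequence in the protein (titin's Ig/PEVK repeats make some tryptic
#' peptides non-unique; downstream quantification excludes `n_loci > 1` by
#' default).
#'
#' @param model An `exon_model`.
#' @param missed_cleavages Maximum number of missed cleavage sites (>= 0).
#' @return Data frame with columns `sequence`, `start_res`, `end_res`,
#'   `n_missed`, `exon_set` (list column of integer vectors), `n_loci`.
#' @export
digest_tryptic <- function(model, missed_cleavages = 0L) {
  stopifnot(inherits(model, "exon_model"), missed_cleavages >= 0L)
  prot <- model$protein
  if (nchar(prot) == 0L) stop("empty protein")
  res <- strsplit(prot, "")[[1]]
  n <- length(res)
  # cleavage site after position i: K/R at i, not P at i+1
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  frag_start <- c(1L, cut_after + 1L)
  frag_end <- c(cut_after, n)
  nf <- length(frag_start)

  rows <- list()
  for (i in seq_len(nf)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nf) break
      rows[[length(rows) + 1L]] <-
        c(start = frag_start[i], end = frag_end[j], miss = m)
    }
  }
  rows <- do.call(rbind, rows)
  seqs <- substring(prot, rows[, "start"], rows[, "end"])
  out <- data.frame(sequence = seqs,
                    start_res = as.integer(rows[, "start"]),
                    end_res = as.integer(rows[, "end"]),
                    n_missed = as.integer(rows[, "miss"]),
                    stringsAsFactors = FALSE)
  out$exon_set <- lapply(seq_len(nrow(out)), function(k) {
    sort(unique(unlist(
      model$residue_exons[out$start_res[k]:out$end_res[k]])))
  })
  out$n_loci <- vapply(out$sequence, function(s) {
    length(find_all_occurrences(s, prot))
  }, integer(1))
  rownames(out) <- NULL
  out
}

# all (possibly overlapping) start positions of `pattern` in `text`
find_all_occurrences <- function(pattern, text) {
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(pattern, substring(text, from), fixed = TRUE)
    if (p < 0L) break
    hits <- c(hits, from + as.integer(p) - 1L)
    from <- from + as.integer(p)  # advance one position: allow overlaps
  }
  hits
}

#' Map an identified peptide back to genomic exons
#'
#' Locates every occurrence of a peptide sequence in the model's protein and
#' returns the union of exon annotations over all loci. `n_loci > 1` flags a
#' peptide that cannot be attributed to a single locus; downstream policy
#' decides whether such peptides enter exon-specific quantification.
#'
#' @param seq Amino-acid string.
#' @param model An `exon_model`.
#' @return List with `sequence`, `start_res`, `end_res` (first locus),
#'   `exon_set` (union over loci), `n_loci`, `loci` (integer start
#'   positions).
#' @export
map_peptide_to_exons <- function(seq, model) {
  stopifnot(inherits(model, "exon_model"),
            is.character(seq), length(seq) == 1L, nzchar(seq))
  loci <- find_all_occurrences(seq, model$protein)
  if (length(loci) == 0L) {
    stop(sprintf("peptide '%s' not found in model protein", seq))
  }
  L <- nchar(seq)
  exon_set <- sort(unique(unlist(lapply(loci, function(s) {
    unlist(model$residue_exons[s:(s + L - 1L)])
  }))))
  list(sequence = seq, start_res = loci[1], end_res = loci[1] + L - 1L,
       exon_set = exon_set, n_loci = length(loci), loci = loci)
}
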