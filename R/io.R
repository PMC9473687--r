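#' Read a transcript or exon sequence set from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Read an exon boundary (or mapping) table
#'
#' Tab- or comma-separated file with columns `index`, `start`, `end` and
#' optionally `genomic_number`; 1-based inclusive transcript coordinates.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_exon_boundaries <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Read a peptide abundance table
#'
#' Expects a delimited file with a peptide-sequence column and one numeric
#' abundance column per sample; any other columns are ignored. Column names
#' can be remapped through `column_map` so exported layouts with different
#' headers can be consumed unchanged.
#'
#' @param path CSV/TSV path.
#' @param groups Named character vector: sample column name -> group label.
#' @param model Optional `exon_model` used to annotate each peptide with its
#'   exon set via [map_peptide_to_exons()]; peptides absent from the model
#'   are dropped with a warning.
#' @param sequence_col Name of the peptide sequence column.
#' @param column_map Optional named character vector renaming file columns
#'   (`new_name = old_name`).
#' @return A `peptide_table`.
#' @export
read_peptide_table <- function(path, groups, model = NULL,
                               sequence_col = "peptide_sequence",
                               column_map = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (new in names(column_map)) {
      names(d)[names(d) == column_map[[new]]] <- new
    }
  }
  if (!sequence_col %in% names(d)) {
    stop("missing peptide sequence column '", sequence_col, "'")
  }
  missing_samples <- setdiff(names(groups), names(d))
  if (length(missing_samples)) {
    stop("sample column(s) absent from file: ",
         paste(missing_samples, collapse = ", "))
  }
  ab <- as.matrix(d[, names(groups), drop = FALSE])
  storage.mode(ab) <- "double"
  peptides <- data.frame(sequence = d[[sequence_col]],
                         stringsAsFactors = FALSE)
  if (!is.null(model)) {
    mapped <- lapply(peptides$sequence, function(s) {
      tryCatch(map_peptide_to_exons(s, model), error = function(e) NULL)
    })
    ok <- !vapply(mapped, is.null, logical(1))
    if (any(!ok)) {
      warning(sum(!ok), " peptide(s) not found in the model protein; dropped")
    }
    peptides <- peptides[ok, , drop = FALSE]
    ab <- ab[ok, , drop = FALSE]
    peptides$exon_set <- lapply(mapped[ok], `[[`, "exon_set")
    peptides$n_loci <- vapply(mapped[ok], `[[`, integer(1), "n_loci")
  } else if ("exon_set" %in% names(d)) {
    peptides$exon_set <- lapply(strsplit(as.character(d$exon_set), ","),
                                as.integer)
    peptides$n_loci <- if ("n_loci" %in% names(d)) d$n_loci else 1L
  } else {
    stop("supply a model or an exon_set column")
  }
  peptide_table(peptides, ab, groups)
}

#' Read a junction count table
#'
#' @param path TSV/CSV with columns `exon`, `sample`, `inclusion_reads`,
#'   `skipping_reads`.
#' @param groups Named character vector: sample -> group label.
#' @return A `junction_counts` object. Malformed rows (non-integer or
#'   negative counts) raise an error naming the offending line numbers.
#' @export
read_junction_counts <- function(path, groups) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  for (col in c("inclusion_reads", "skipping_reads")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop("malformed ", col, " at data line(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    d[[col]] <- as.integer(v)
  }
  junction_counts(d, groups)
}

#' Read multichannel line profiles
#'
#' Delimited file with a `position` index column (ignored beyond ordering)
#' and one intensity column per channel.
#'
#' @param path TSV/CSV path.
#' @param pixel_size Pixel size in nm.
#' @return A `line_profile_set`.
#' @export
read_line_profiles <- function(path, pixel_size) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if ("position" %in% names(d)) {
    d <- d[order(d$position), setdiff(names(d), "position"), drop = FALSE]
  }
  line_profile_set(as.list(d), pixel_size)
}

#' Serialize an exon model to JSON
#'
#' Layout: `transcript_id`, `cds_start`, `cds_end`, `protein`, `exons`
#' (records with `index`, `start`, `end`, `genomic_number`, `sequence`) and
#' `residue_exons` (array of integer arrays, one per residue).
#'
#' @param model An `exon_model`.
#' @param path Output path.
#' @export
write_exon_model <- function(model, path) {
  stopifnot(inherits(model, "exon_model"))
  obj <- list(transcript_id = model$transcript_id,
              cds_start = model$cds_start, cds_end = model$cds_end,
              protein = model$protein,
              exons = model$exons,
              residue_exons = model$residue_exons)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an exon model written by [write_exon_model()]
#'
#' @param path JSON path.
#' @return An `exon_model`.
#' @export
read_exon_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(transcript_id = obj$transcript_id,
         exons = as.data.frame(obj$exons),
         cds_start = as.integer(obj$cds_start),
         cds_end = as.integer(obj$cds_end),
         protein = obj$protein,
         residue_exons = lapply(obj$residue_exons, as.integer)),
    class = "exon_model")
}
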