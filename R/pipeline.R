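#' Read a run configuration
#'
#' YAML (or JSON) configuration shared by the pipeline runners. Recognized
#' fields, with the analysis defaults: `filter_threshold` (1.5e7),
#' `constitutive_region` (256-363), `regions` (named exon ranges; default
#' the proximal-Ig events 52-69, 70-79, 80-88), `alpha` (0.05),
#' `n_regions_tested` (2), `group_a`/`group_b` (control/ko),
#' `membership` ("all"), plus input paths used by the runners.
#'
#' @param path YAML/JSON file path, or a list already in memory.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(filter_threshold = 1.5e7,
                   constitutive_region = c(256L, 363L),
                   regions = titin_proximal_ig_events(),
                   alpha = 0.05, n_regions_tested = 2L,
                   group_a = "control", group_b = "ko",
                   membership = "all",
                   min_separation_nm = 1000,
                   epitope_min_separation_nm = 250,
                   min_prominence = 0.2,
                   max_half_sarcomere_nm = 1500,
                   length_window_nm = c(1000, 5000),
                   pixel_size_nm = 20)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg$regions <- lapply(cfg$regions, as.integer)
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  bad <- vapply(cfg$regions, function(r) {
    length(r) != 2L || r[2] < r[1]
  }, logical(1))
  if (any(bad)) stop("invalid exon range(s): ",
                     paste(names(cfg$regions)[bad], collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

report_skeleton <- function(stage, config) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  list(stage = stage,
       package_version = as.character(utils::packageVersion("titinsplice")),
       config = cfg)
}

#' Run the proteomics quantification stage
#'
#' Filter to robust peak areas, normalize to the constitutive region,
#' summarize and test every configured exon region. Accepts either a
#' `peptide_table` (`table` argument) or a config with `peptide_table_path` +
#' `groups`.
#'
#' @param config A `run_config` (or list/path coercible by
#'   [read_run_config()]).
#' @param table Optional in-memory `peptide_table` (overrides paths).
#' @param model Optional `exon_model` for peptide annotation when reading
#'   from file.
#' @return Report list: per-region summaries plus peptide counts before and
#'   after filtering and the covered-exon count.
#' @export
run_proteomics <- function(config, table = NULL, model = NULL) {
  config <- read_run_config(config)
  if (is.null(table)) {
    if (is.null(config$peptide_table_path)) {
      stop("config lacks peptide_table_path and no table was supplied")
    }
    if (is.null(config$groups)) stop("config lacks the sample group map")
    table <- read_peptide_table(config$peptide_table_path,
                                unlist(config$groups), model = model)
  }
  report <- report_skeleton("proteomics", config)
  report$n_peptides_input <- nrow(table$abundance)
  filtered <- filter_low_abundance(table, config$group_a,
                                   config$filter_threshold)
  report$n_peptides_retained <- nrow(filtered$abundance)
  report$n_covered_exons <- count_covered_exons(filtered)
  normalized <- normalize_to_constitutive(filtered,
                                          config$constitutive_region)
  report$regions <- lapply(config$regions, function(r) {
    unclass(compare_region(normalized, r, config$group_a, config$group_b,
                           n_regions_tested = config$n_regions_tested,
                           alpha = config$alpha,
                           membership = config$membership))
  })
  report
}

#' Run the splicing PSI stage
#'
#' PSI per exon and sample, per-exon delta PSI, and event-level aggregation
#' with group tests. Accepts an in-memory `junction_counts` or a config with
#' `junction_counts_path` + `groups`.
#'
#' @param config A `run_config` (or list/path).
#' @param counts Optional `junction_counts`.
#' @return Report list with `delta_psi` (per exon) and `events`.
#' @export
run_splicing <- function(config, counts = NULL) {
  config <- read_run_config(config)
  if (is.null(counts)) {
    if (is.null(config$junction_counts_path)) {
      stop("config lacks junction_counts_path and no counts were supplied")
    }
    if (is.null(config$groups)) stop("config lacks the sample group map")
    counts <- read_junction_counts(config$junction_counts_path,
                                   unlist(config$groups))
  }
  report <- report_skeleton("splicing", config)
  psi <- compute_psi(counts)
  report$n_exons <- nrow(psi$psi)
  report$n_exons_defined <- sum(rowSums(!is.na(psi$psi)) > 0)
  report$delta_psi <- delta_psi(psi, config$group_a, config$group_b)
  ev <- aggregate_events(psi, config$regions, config$group_a, config$group_b)
  report$events <- ev$tests
  report$event_sample_psi <- ev$sample_psi
  report
}

#' Run the morphometry stage
#'
#' Detects Z-line and epitope peaks in each profile set, measures sarcomere
#' lengths and proximal-Ig epitope distances, and compares length variance
#' between the two groups with an F-test.
#'
#' @param config A `run_config` (or list/path).
#' @param profiles_a,profiles_b `line_profile_set` objects (group a/b), or
#'   set `profile_path_a`/`profile_path_b` in the config.
#' @param z_channel,epitope_channel Channel names.
#' @return Report list with per-group length and epitope-distance summaries
#'   and the `variance_test`.
#' @export
run_morphometry <- function(config, profiles_a = NULL, profiles_b = NULL,
                            z_channel = "actinin", epitope_channel = "n2a") {
  config <- read_run_config(config)
  if (is.null(profiles_a)) {
    profiles_a <- read_line_profiles(config$profile_path_a,
                                     config$pixel_size_nm)
  }
  if (is.null(profiles_b)) {
    profiles_b <- read_line_profiles(config$profile_path_b,
                                     config$pixel_size_nm)
  }
  measure <- function(p) {
    z <- detect_peaks(p$channels[[z_channel]], p$pixel_size,
                      config$min_separation_nm, config$min_prominence)
    if (length(z) == 0L) warning("no Z-line peaks detected in a profile")
    len <- sarcomere_lengths(z, config$length_window_nm[1],
                             config$length_window_nm[2])
    out <- list(n_z_peaks = length(z), lengths_nm = as.numeric(len),
                n_excluded = attr(len, "n_excluded"),
                length_summary = morphometry_summary(as.numeric(len)))
    if (epitope_channel %in% names(p$channels)) {
      e <- detect_peaks(p$channels[[epitope_channel]], p$pixel_size,
                        config$epitope_min_separation_nm,
                        config$min_prominence)
      d <- epitope_distance(z, e, config$max_half_sarcomere_nm)
      out$epitope_distances_nm <- as.numeric(d)
      out$epitope_summary <- morphometry_summary(as.numeric(d))
    }
    out
  }
  report <- report_skeleton("morphometry", config)
  report$group_a <- measure(profiles_a)
  report$group_b <- measure(profiles_b)
  report$variance_test <- unclass(
    variance_test(report$group_a$lengths_nm, report$group_b$lengths_nm))
  report
}

#' Write a pipeline report to disk
#'
#' Machine-readable JSON plus, when the report carries tabular elements,
#' companion TSV files next to it.
#'
#' @param report A report list from one of the `run_*` functions.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  for (nm in intersect(c("delta_psi", "events"), names(report))) {
    utils::write.table(report[[nm]],
                       sub("\\.json$", paste0("_", nm, ".tsv"), path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
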