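#' Sampled species richness
#'
#' Counts the taxa recorded as present at each site: abundance greater than
#' zero, or a presence flag. Richness is insensitive to abundance
#' magnitudes and to the order of records.
#'
#' @param samples long-format community tibble with columns `site_id`,
#'   `taxon`, `abundance` (non-negative; presence may be coded as 1).
#' @return tibble with `site_id` and integer `richness`.
#' @export
species_richness <- function(samples) {
  check_community(samples)
  samples |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(richness = sum(.data$abundance > 0), .groups = "drop")
}

check_community <- function(samples) {
  need <- c("site_id", "taxon", "abundance")
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0) {
    abort(sprintf("community table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(samples$abundance < 0, na.rm = TRUE)) {
    abort("abundances must be non-negative")
  }
  invisible(samples)
}

#' Effort-corrected total abundance
#'
#' Sums the recorded abundances per site. Where the measurement is
#' effort-sensitive and sampling effort differs among sites within the
#' study, the sum is divided by the site's relative effort — its effort as
#' a proportion of the effort of the most-sampled site in the same study —
#' so that more thinly sampled sites are scaled up.
#'
#' @param samples long community tibble with columns `site_id`, `taxon`,
#'   `abundance`, `effort` (> 0), `study_id`, and optionally a logical
#'   `effort_sensitive` flag (default: correction applies).
#' @return tibble with `site_id`, `study_id`, `abundance` (corrected total).
#' @export
effort_corrected_abundance <- function(samples) {
  check_community(samples)
  if (!all(c("effort", "study_id") %in% names(samples))) {
    abort("effort_corrected_abundance needs 'effort' and 'study_id' columns")
  }
  if (any(samples$effort <= 0)) abort("effort must be positive")
  if (!"effort_sensitive" %in% names(samples)) samples$effort_sensitive <- TRUE
  per_site <- samples |>
    dplyr::group_by(.data$study_id, .data$site_id) |>
    dplyr::summarise(total = sum(.data$abundance),
                     effort = .data$effort[1],
                     sensitive = any(.data$effort_sensitive),
                     .groups = "drop_last") |>
    dplyr::mutate(
      max_effort = max(.data$effort),
      correct = .data$sensitive & dplyr::n_distinct(.data$effort) > 1,
      abundance = ifelse(.data$correct,
                         .data$total / (.data$effort / .data$max_effort),
                         .data$total)
    ) |>
    dplyr::ungroup()
  per_site |>
    dplyr::select("site_id", "study_id", "abundance")
}

#' Rescale and log-transform abundances within studies
#'
#' Divides each site's total abundance by the maximum abundance within its
#' study and takes log_e of the rescaled value plus 0.01 (the offset that
#' handles zero abundances). The transform is strictly increasing within a
#' study; the study maximum always maps to log_e(1.01). Studies whose
#' maximum abundance is zero cannot be rescaled and are flagged (column
#' `usable = FALSE`, transformed value `NA`) rather than silently dropped.
#'
#' @param abundance_tbl tibble with `site_id`, `study_id`, `abundance`.
#' @param offset additive offset inside the log (default 0.01).
#' @return input tibble with `log_abundance` and logical `usable` added.
#' @export
rescale_log_abundance <- function(abundance_tbl, offset = 0.01) {
  stopifnot(all(c("site_id", "study_id", "abundance") %in%
                  names(abundance_tbl)))
  out <- abundance_tbl |>
    dplyr::group_by(.data$study_id) |>
    dplyr::mutate(
      usable = max(.data$abundance) > 0,
      log_abundance = ifelse(.data$usable,
                             log(.data$abundance / max(.data$abundance) +
                                   offset),
                             NA_real_)
    ) |>
    dplyr::ungroup()
  if (any(!out$usable)) {
    warn(sprintf(
      "%d study(ies) with zero maximum abundance flagged unusable: %s",
      dplyr::n_distinct(out$study_id[!out$usable]),
      paste(unique(out$study_id[!out$usable]), collapse = ", ")
    ))
  }
  out
}

#' Relative community abundance-weighted average range size (RCAR)
#'
#' The abundance-weighted arithmetic mean of the range sizes of the taxa
#' present at each site. Higher values indicate communities dominated by
#' geographically widespread species (a biotic-homogenization proxy); the
#' models downstream consume log10 of this value. RCAR is invariant to a
#' uniform rescaling of the abundances and always lies between the smallest
#' and largest range among the present taxa. Occurrence-only data (all
#' presences coded 1) degrade gracefully to an unweighted mean.
#'
#' @param samples long community tibble (`site_id`, `taxon`, `abundance`).
#' @param ranges tibble with `taxon` and positive `range_size`.
#' @return tibble with `site_id` and `rcar`. Sites with zero total
#'   abundance get `NA` and a warning; taxa present in samples but missing
#'   from `ranges` are an error naming the taxa.
#' @export
rcar <- function(samples, ranges) {
  check_community(samples)
  stopifnot(all(c("taxon", "range_size") %in% names(ranges)))
  if (any(ranges$range_size <= 0)) abort("range sizes must be positive")
  present <- samples |> dplyr::filter(.data$abundance > 0)
  missing <- setdiff(unique(present$taxon), ranges$taxon)
  if (length(missing) > 0) {
    abort(sprintf("no range size for sampled taxa: %s",
                  paste(sort(missing), collapse = ", ")))
  }
  out <- samples |>
    dplyr::left_join(ranges, by = "taxon") |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      total = sum(.data$abundance),
      wsum = sum(.data$abundance * .data$range_size),
      .groups = "drop"
    ) |>
    dplyr::mutate(rcar = ifelse(.data$total > 0, .data$wsum / .data$total,
                                NA_real_))
  if (any(is.na(out$rcar))) {
    warn(sprintf("%d site(s) with zero total abundance have undefined RCAR",
                 sum(is.na(out$rcar))))
  }
  out |> dplyr::select("site_id", "rcar")
}

#' Compute all three site metrics from community samples
#'
#' Convenience wrapper chaining [species_richness()],
#' [effort_corrected_abundance()] plus [rescale_log_abundance()], and
#' [rcar()] into one per-site metrics table.
#'
#' @param samples long community tibble (`site_id`, `taxon`, `abundance`,
#'   `effort`, `study_id`, optional `effort_sensitive`).
#' @param ranges range-size tibble (`taxon`, `range_size`).
#' @return tibble with one row per site: richness, abundance,
#'   log_abundance, rcar, log10_rcar.
#' @export
site_metrics <- function(samples, ranges) {
  if (!"study_id" %in% names(samples)) samples$study_id <- "study1"
  if (!"effort" %in% names(samples)) samples$effort <- 1
  ab <- effort_corrected_abundance(samples) |> rescale_log_abundance()
  species_richness(samples) |>
    dplyr::left_join(ab, by = "site_id") |>
    dplyr::left_join(rcar(samples, ranges), by = "site_id") |>
    dplyr::mutate(log10_rcar = log10(.data$rcar))
}
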