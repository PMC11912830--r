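# File formats and empirical-pipeline preprocessing: IBD segment tables,
# sample metadata, genetic maps, relatedness filtering, grouping dated
# samples into generation windows, trajectory output.

#' Read an IBD segment table
#'
#' Tab-separated with a header; required columns `id1`, `id2`, `chrom`,
#' `length_cm`; optional `start_cm` / `end_cm`. Malformed rows (non-positive
#' length, identical ids, start/end inconsistent with length) are rejected
#' with their line numbers.
#'
#' @param path file path.
#' @return data.frame of validated segment records.
#' @export
read_ibd_segments <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "")
  req <- c("id1", "id2", "chrom", "length_cm")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop_domain("missing required column(s): ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(tab)) + 1L  # header is line 1
  bad <- !is.finite(tab$length_cm) | tab$length_cm <= 0
  bad_same <- as.character(tab$id1) == as.character(tab$id2)
  bad_span <- rep(FALSE, nrow(tab))
  if (all(c("start_cm", "end_cm") %in% names(tab)))
    bad_span <- is.finite(tab$start_cm) & is.finite(tab$end_cm) &
      abs((tab$end_cm - tab$start_cm) - tab$length_cm) > 0.01
  problems <- bad | bad_same | bad_span
  if (any(problems))
    stop_domain("malformed segment row(s) at line(s): ",
                paste(head(line[problems], 10), collapse = ", "),
                " (non-positive length, id1 == id2, or end - start != length)")
  tab$chrom <- as.character(tab$chrom)
  tab$id1 <- as.character(tab$id1)
  tab$id2 <- as.character(tab$id2)
  tab
}

#' Write an IBD segment table
#'
#' @param segments data.frame of segment records.
#' @param path output path.
#' @export
write_ibd_segments <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with header; required columns `id`, `date`, `coverage`. The
#' `date_unit` argument (or an optional `date_unit` column with values `"BP"`
#' or `"CE"`) states whether dates are years before present or calendar years.
#'
#' @param path file path.
#' @param date_unit `"BP"` (years before present) or `"CE"` (calendar years);
#'   overridden by a `date_unit` column if present.
#' @return data.frame with columns `id`, `date`, `date_unit`, `coverage`.
#' @export
read_sample_metadata <- function(path, date_unit = c("BP", "CE")) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  date_unit <- match.arg(date_unit)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("id", "date", "coverage")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop_domain("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"date_unit" %in% names(tab)) tab$date_unit <- date_unit
  if (!all(tab$date_unit %in% c("BP", "CE")))
    stop_domain("date_unit must be 'BP' or 'CE'")
  if (anyDuplicated(tab$id)) stop_domain("duplicate individual ids in metadata")
  if (!all(is.finite(tab$date))) stop_domain("dates must be finite")
  tab$id <- as.character(tab$id)
  tab[, c("id", "date", "date_unit", "coverage")]
}

#' Read a genetic map table
#'
#' Tab-separated with header; columns `chrom`, `length_morgan`.
#'
#' @param path file path.
#' @return a [chromosome_map()].
#' @export
read_chromosome_map <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chrom", "length_morgan") %in% names(tab)))
    stop_domain("map must have columns: chrom, length_morgan")
  chromosome_map(tab$length_morgan, labels = tab$chrom)
}

#' Write a fitted trajectory with confidence envelope
#'
#' Columns: `generation` (before the most recent sample set), `ne` (diploid),
#' `ci_low`, `ci_high` (NA without a bootstrap).
#'
#' @param fit an `ne_fit` from [fit_trajectory()].
#' @param path output path.
#' @param boot optional `ne_bootstrap` from [bootstrap_ci()].
#' @export
write_trajectory <- function(fit, path, boot = NULL) {
  out <- data.frame(generation = seq_along(fit$ne) - 1L, ne = fit$ne,
                    ci_low = if (is.null(boot)) NA_real_ else boot$ci_low,
                    ci_high = if (is.null(boot)) NA_real_ else boot$ci_high)
  write.table(format(out, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter close relatives from a sample
#'
#' Flags a pair of individuals as close kin when they share at least
#' `min_count` IBD segments longer than `min_cm`, or when the summed length
#' of their segments longer than `min_cm` exceeds `sum_cm`. From each flagged
#' pair the lower-coverage member is removed (ties broken by lexicographic
#' id), iterating until no flagged pair remains among the kept individuals.
#'
#' @param segments data.frame of segment records.
#' @param meta metadata (needs `id` and `coverage`).
#' @param min_count segment-count threshold (default 3).
#' @param min_cm length threshold in cM for counted segments (default 12).
#' @param sum_cm summed-length threshold in cM (default 100).
#' @return list with `kept` (ids), `removed` (ids) and `flagged_pairs`
#'   (data.frame report).
#' @export
relatedness_filter <- function(segments, meta, min_count = 3, min_cm = 12,
                               sum_cm = 100) {
  cov <- setNames(meta$coverage, meta$id)
  long <- segments[segments$length_cm > min_cm, , drop = FALSE]
  key <- paste(pmin(long$id1, long$id2), pmax(long$id1, long$id2), sep = "\r")
  n_seg <- tapply(long$length_cm, key, length)
  s_seg <- tapply(long$length_cm, key, sum)
  flagged <- names(n_seg)[n_seg >= min_count | s_seg > sum_cm]
  fp <- do.call(rbind, strsplit(flagged, "\r", fixed = TRUE))
  report <- if (length(flagged) > 0)
    data.frame(id1 = fp[, 1], id2 = fp[, 2],
               n_long = as.integer(n_seg[flagged]),
               sum_long_cm = as.numeric(s_seg[flagged]))
  else data.frame(id1 = character(), id2 = character(),
                  n_long = integer(), sum_long_cm = numeric())
  kept <- unique(meta$id)
  removed <- character()
  repeat {
    active <- report[report$id1 %in% kept & report$id2 %in% kept, , drop = FALSE]
    if (nrow(active) == 0) break
    p <- active[1, ]
    c1 <- cov[p$id1] %||% NA_real_
    c2 <- cov[p$id2] %||% NA_real_
    drop_id <- if (isTRUE(c1 < c2)) p$id1
      else if (isTRUE(c2 < c1)) p$id2
      else max(p$id1, p$id2)  # coverage tie: drop the lexicographically later id
    kept <- setdiff(kept, drop_id)
    removed <- c(removed, drop_id)
  }
  list(kept = kept, removed = removed, flagged_pairs = report)
}

#' Group dated samples into generation windows
#'
#' Converts dates to generations before the most recent individual (at
#' `generation_time` years per generation), floors them into consecutive
#' windows of `window` generations anchored at the most recent date, and
#' builds a sampling scheme with one set per non-empty window at time
#' `window_index * window` generations.
#'
#' @param meta metadata with `id`, `date`, `date_unit` (`"BP"` or `"CE"`).
#' @param window window width in generations (default 5).
#' @param generation_time years per generation (default 29).
#' @return a [sampling_scheme()] with ids; attribute `assignment` maps each
#'   individual to its set and generation value.
#' @export
group_by_generations <- function(meta, window = 5, generation_time = 29) {
  if (nrow(meta) == 0) stop_domain("empty metadata")
  if (!"date_unit" %in% names(meta)) stop_domain("metadata must carry date_unit")
  years_bp <- ifelse(meta$date_unit == "BP", meta$date, 1950 - meta$date)
  # years before the most recent individual
  rel_years <- years_bp - min(years_bp)
  gens <- rel_years / generation_time
  win <- floor(gens / window)
  sets <- sort(unique(win))
  ids <- lapply(sets, function(s) as.character(meta$id[win == s]))
  scheme <- sampling_scheme(times = as.integer(sets * window),
                            sizes = lengths(ids), ids = ids)
  attr(scheme, "assignment") <- data.frame(id = as.character(meta$id),
                                           generations = gens,
                                           set = match(win, sets))
  scheme
}
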