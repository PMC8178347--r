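#' Mean read quality on the phred scale
#'
#' Converts each phred+33 symbol to an error probability, averages the
#' probabilities across the read, and converts back:
#' `-10 * log10(mean(p))`. Averaging on the probability scale (rather than
#' averaging phred scores) matches how long-read QC tools summarise read
#' accuracy; a few very bad bases dominate, as they should.
#'
#' @param qual Character vector of phred+33 quality strings.
#' @return Numeric vector of read-level phred qualities.
#' @export
mean_read_quality <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || nchar(q) == 0) abort("empty quality string")
    p <- 10^(-(utf8ToInt(q) - 33) / 10)
    -10 * log10(mean(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Quality-control profile
#'
#' @param name Profile label.
#' @param min_quality Read-level phred threshold.
#' @param quality_strict If TRUE the comparison is `quality > min_quality`
#'   (strict), otherwise `quality >= min_quality`.
#' @param min_length,max_length Inclusive length window in bp
#'   (`max_length = NULL` leaves the window open above).
#' @return A `qc_profile` object.
#' @export
qc_profile <- function(name, min_quality, quality_strict = FALSE,
                       min_length = 1, max_length = NULL) {
  if (min_length < 1) abort("min_length must be >= 1")
  if (!is.null(max_length) && max_length < min_length) {
    abort("max_length must be >= min_length")
  }
  structure(list(name = name, min_quality = min_quality,
                 quality_strict = quality_strict,
                 min_length = as.integer(min_length),
                 max_length = if (is.null(max_length)) NULL
                              else as.integer(max_length)),
            class = "qc_profile")
}

#' Named QC presets for each sequencing pipeline
#'
#' Final-stage presets: `mock_16S` and `mock_rrn` (quality > 12, lengths
#' 1300-1950 and 3500-5000 bp), `fecal_16S` and `fecal_rrn` (quality > 11,
#' same windows), `shotgun` (quality >= 10, length >= 1000 bp). Pretrim
#' presets `pretrim_16S` / `pretrim_rrn` (quality >= 10, length >= 1300 /
#' 3500 bp) reproduce the first-pass filter applied before subsampling.
#' The "scores of 10" stage is read as non-strict and the "> 12" / "> 11"
#' stages as strict, following the wording of each threshold; both are
#' switchable via [qc_profile()].
#'
#' @param name Preset name; omit to get the list of all presets.
#' @return A `qc_profile`, or a named list of them.
#' @export
qc_presets <- function(name = NULL) {
  presets <- list(
    pretrim_16S = qc_profile("pretrim_16S", 10, FALSE, 1300, NULL),
    pretrim_rrn = qc_profile("pretrim_rrn", 10, FALSE, 3500, NULL),
    mock_16S = qc_profile("mock_16S", 12, TRUE, 1300, 1950),
    mock_rrn = qc_profile("mock_rrn", 12, TRUE, 3500, 5000),
    fecal_16S = qc_profile("fecal_16S", 11, TRUE, 1300, 1950),
    fecal_rrn = qc_profile("fecal_rrn", 11, TRUE, 3500, 5000),
    shotgun = qc_profile("shotgun", 10, FALSE, 1000, NULL))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset: ", name, " (available: ",
                 paste(names(presets), collapse = ", "), ")"))
  }
  presets[[name]]
}

#' Filter reads by quality and length
#'
#' A read passes when its [mean_read_quality()] satisfies the profile's
#' quality comparison and its length lies inside the inclusive length
#' window. Rejection reasons partition the rejected reads; a read failing
#' both checks is counted under `length`.
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @param profile A [qc_profile()] or preset name (see [qc_presets()]).
#' @return List with `passed` (read tibble), `rejected` (tibble `reason`,
#'   `n`), and `n_input`.
#' @export
filter_reads <- function(reads, profile) {
  if (is.character(profile)) profile <- qc_presets(profile)
  stopifnot(inherits(profile, "qc_profile"))
  reads <- as_tibble(reads)
  len <- nchar(reads$seq)
  len_ok <- len >= profile$min_length &
    (is.null(profile$max_length) | len <= (profile$max_length %||% Inf))
  q <- mean_read_quality(reads$qual)
  q_ok <- if (profile$quality_strict) q > profile$min_quality
          else q >= profile$min_quality
  reason <- dplyr::case_when(!len_ok ~ "length", !q_ok ~ "quality",
                             TRUE ~ "pass")
  list(
    passed = reads[reason == "pass", ],
    rejected = dplyr::count(
      tibble(reason = reason[reason != "pass"]), .data$reason, name = "n"),
    n_input = nrow(reads))
}

#' Subsample reads without replacement
#'
#' Uniform sampling without replacement; output preserves the input order
#' of the selected reads and is deterministic for a fixed seed.
#'
#' @param reads Read tibble.
#' @param n Number of reads to keep (must not exceed the number
#'   available).
#' @param seed Integer seed.
#' @return Subsampled read tibble.
#' @export
subsample_reads <- function(reads, n, seed) {
  reads <- as_tibble(reads)
  if (n > nrow(reads)) {
    abort(sprintf("requested %d reads but only %d are available",
                  n, nrow(reads)))
  }
  withr::with_seed(seed, {
    keep <- sort(sample(nrow(reads), n))
    reads[keep, ]
  })
}

#' QC report for a read set
#'
#' @param reads Read tibble.
#' @param bins Number of histogram bins.
#' @return List with `n_reads`, length and quality summaries and
#'   histograms, suitable for `jsonlite::write_json()`.
#' @export
qc_report <- function(reads, bins = 30) {
  len <- nchar(reads$seq)
  q <- mean_read_quality(reads$qual)
  hist_of <- function(x) {
    h <- graphics::hist(x, breaks = bins, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  list(n_reads = nrow(reads),
       length = list(min = min(len), median = stats::median(len),
                     max = max(len), histogram = hist_of(len)),
       quality = list(min = min(q), median = stats::median(q),
                      max = max(q), histogram = hist_of(q)))
}
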