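#' Reads-per-million normalisation
#'
#' `RPM = n_isoform / n_all * 1e6`, where `n_all` is the total number of
#' mapped reads in the sample.
#'
#' @param n_isoform Read count of the isoform in the sample.
#' @param n_all Total mapped reads in the sample (> 0).
#' @return RPM as a double (vectorised).
#' @export
#' @examples
#' rpm(250, 2e6)  # 125
rpm <- function(n_isoform, n_all) {
  if (any(n_all <= 0)) stop("empty sample: n_all must be > 0", call. = FALSE)
  if (any(n_isoform < 0) || any(n_isoform > n_all))
    stop("n_isoform must lie in [0, n_all]", call. = FALSE)
  n_isoform / n_all * 1e6
}

#' Cumulative RPM across samples
#'
#' Sum of per-sample RPM values over the samples in which the isoform was
#' detected.
#'
#' @param rpms Numeric vector of per-sample RPM values (all >= 0).
#' @return Their sum (0 for an empty vector).
#' @export
cumulative_rpm <- function(rpms) {
  if (any(rpms < 0)) stop("RPM values must be non-negative", call. = FALSE)
  sum(rpms)
}

#' Divided RPM across samples
#'
#' Cumulative RPM divided by `n`. By the detected-samples convention
#' (default) `n` is the number of samples in which the isoform was
#' detected (count > 0); the all-samples convention divides by the total
#' number of samples instead.
#'
#' @param rpms Per-sample RPM values for the samples where detected.
#' @param n_mode `"detected"` or `"all"`.
#' @param n_samples Total sample count (required for `n_mode = "all"`).
#' @return Divided RPM.
#' @export
divided_rpm <- function(rpms, n_mode = c("detected", "all"),
                        n_samples = NULL) {
  n_mode <- match.arg(n_mode)
  n <- if (n_mode == "detected") length(rpms) else n_samples
  if (is.null(n) || n == 0L) stop("n must be positive", call. = FALSE)
  cumulative_rpm(rpms) / n
}

#' Build the per-isoform expression table
#'
#' One row per isoform call; one RPM column per sample (`rpm_<sample>`),
#' computed against that sample's `total_mapped`, plus `cumulative_rpm`,
#' `divided_rpm` and `n_samples_detected`.
#'
#' @param calls Isoform calls (the `calls` element of [call_isoforms()]),
#'   or any data.frame with a `tag_sequence` column.
#' @param tags Long tag data.frame (`sequence`, `sample_id`, `count`).
#' @param samples Sample sheet with completed `total_mapped` (see
#'   [complete_totals()]).
#' @param n_mode Divided-RPM convention, see [divided_rpm()].
#' @return The `calls` data.frame extended with expression columns.
#' @export
build_expression_table <- function(calls, tags, samples,
                                   n_mode = c("detected", "all")) {
  n_mode <- match.arg(n_mode)
  unknown <- setdiff(unique(tags$sample_id), samples$sample_id)
  if (length(unknown))
    stop("tag counts refer to unknown sample '", unknown[1], "'",
         call. = FALSE)
  sample_ids <- samples$sample_id
  totals <- setNames(samples$total_mapped, sample_ids)
  # counts matrix: isoform x sample
  cnt <- matrix(0L, nrow = nrow(calls), ncol = length(sample_ids),
                dimnames = list(NULL, sample_ids))
  sub <- tags[tags$sequence %in% calls$tag_sequence, , drop = FALSE]
  if (nrow(sub)) {
    i <- match(sub$sequence, calls$tag_sequence)
    j <- match(sub$sample_id, sample_ids)
    cnt[cbind(i, j)] <- cnt[cbind(i, j)] + sub$count
  }
  rpm_mat <- sweep(cnt, 2L, totals, "/") * 1e6
  detected <- cnt > 0L
  n_det <- rowSums(detected)
  cum <- rowSums(rpm_mat * detected)
  div <- ifelse(n_det > 0,
                cum / (if (n_mode == "detected") pmax(n_det, 1L)
                       else length(sample_ids)),
                0)
  out <- calls
  for (s in sample_ids) out[[paste0("rpm_", s)]] <- rpm_mat[, s]
  out$cumulative_rpm <- cum
  out$divided_rpm <- div
  out$n_samples_detected <- as.integer(n_det)
  out
}
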