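#' Extract per-block features from a synthetic cohort
#'
#' Runs the cardiovascular pipeline (and, when EEG was generated, the
#' EEG pipeline) on every participant x condition block and returns one
#' tidy row per block.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param spectral Compute the frequency-domain HRV summary (needs
#'   blocks >= 120 s; `FALSE` keeps only mean HR / SDNN / RMSSD).
#' @param ... Passed to [spectral_summary()].
#' @return data.frame with columns `participant`, `condition` and one
#'   column per feature.
#' @export
extract_cohort_features <- function(cohort, spectral = TRUE, ...) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- list()
  for (p in cohort$participants) {
    for (cond in names(p$conditions)) {
      rec <- p$conditions[[cond]]
      row <- data.frame(participant = p$id, condition = cond)
      if (!is.null(rec$rri)) {
        td <- time_domain_summary(rec$rri)
        row <- cbind(row, as.data.frame(td))
        if (spectral) {
          row <- cbind(row, as.data.frame(spectral_summary(rec$rri, ...)))
        }
      }
      if (!is.null(rec$eeg)) {
        row <- cbind(row, eeg_feature_summary(rec$eeg))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape tidy cohort features into a participants x conditions matrix
#'
#' @param features Tidy data.frame from [extract_cohort_features()].
#' @param feature Feature column name (e.g. `"mean_hr"`,
#'   `"frontal_theta"`).
#' @param conditions Condition column order.
#' @return Numeric matrix, participants x conditions.
#' @export
feature_matrix <- function(features, feature,
                           conditions = c("baseline", "easy", "medium",
                                          "hard")) {
  stopifnot(feature %in% names(features))
  parts <- sort(unique(features$participant))
  m <- matrix(NA_real_, length(parts), length(conditions),
              dimnames = list(parts, conditions))
  for (i in seq_len(nrow(features))) {
    cond <- as.character(features$condition[i])
    if (!cond %in% conditions) next
    m[as.character(features$participant[i]), cond] <- features[[feature]][i]
  }
  m
}
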