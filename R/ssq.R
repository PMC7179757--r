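#' Simulator Sickness Questionnaire loading matrix
#'
#' The published 16 x 3 binary loading matrix of the SSQ: each of the 16
#' symptom items loads one or two of the clusters nausea (N), oculomotor
#' (O) and disorientation (D).  Item names are spelled as in the
#' instrument; each cluster is loaded by exactly seven items.
#'
#' @return 16 x 3 integer matrix with item rownames and columns
#'   `nausea`, `oculomotor`, `disorientation`.
#' @export
ssq_loadings <- function() {
  items <- c("general_discomfort", "fatigue", "headache", "eyestrain",
             "difficulty_focusing", "increased_salivation", "sweating",
             "nausea", "difficulty_concentrating", "fullness_of_head",
             "blurred_vision", "dizziness_eyes_open",
             "dizziness_eyes_closed", "vertigo", "stomach_awareness",
             "burping")
  m <- matrix(0L, 16, 3, dimnames = list(items, c("nausea", "oculomotor",
                                                  "disorientation")))
  m[c("general_discomfort", "increased_salivation", "sweating", "nausea",
      "difficulty_concentrating", "stomach_awareness", "burping"),
    "nausea"] <- 1L
  m[c("general_discomfort", "fatigue", "headache", "eyestrain",
      "difficulty_focusing", "difficulty_concentrating", "blurred_vision"),
    "oculomotor"] <- 1L
  m[c("difficulty_focusing", "nausea", "fullness_of_head", "blurred_vision",
      "dizziness_eyes_open", "dizziness_eyes_closed", "vertigo"),
    "disorientation"] <- 1L
  m
}

#' Score a Simulator Sickness Questionnaire response
#'
#' Items are rated 0-3 (none / slight / moderate / severe).  Raw cluster
#' sums come from the binary loading matrix; scale scores apply the
#' published weights: nausea = raw_N x 9.54, oculomotor = raw_O x 7.58,
#' disorientation = raw_D x 13.92, and total severity =
#' (raw_N + raw_O + raw_D) x 3.74.
#'
#' @param response Numeric vector of 16 item ratings in `{0, 1, 2, 3}`;
#'   if named, names must match `rownames(ssq_loadings())` (any order).
#' @return An object of class `ssq_scores`: list with `nausea`,
#'   `oculomotor`, `disorientation`, `total` and the raw cluster sums in
#'   `raw`.
#' @examples
#' r <- stats::setNames(rep(0, 16), rownames(ssq_loadings()))
#' r["increased_salivation"] <- 1
#' score_ssq(r)$nausea  # 9.54
#' @export
score_ssq <- function(response) {
  load <- ssq_loadings()
  if (length(response) != 16) stop("an SSQ response has exactly 16 items")
  if (!is.null(names(response))) {
    missing <- setdiff(rownames(load), names(response))
    if (length(missing)) {
      stop("missing item(s): ", paste(missing, collapse = ", "))
    }
    response <- response[rownames(load)]
  }
  if (any(!response %in% 0:3)) {
    stop("item ratings must be integers in {0, 1, 2, 3}")
  }
  raw <- as.vector(t(load) %*% response)
  names(raw) <- colnames(load)
  structure(list(nausea = raw[["nausea"]] * 9.54,
                 oculomotor = raw[["oculomotor"]] * 7.58,
                 disorientation = raw[["disorientation"]] * 13.92,
                 total = sum(raw) * 3.74,
                 raw = raw),
            class = "ssq_scores")
}

#' Flag SSQ scale scores against reference cut-offs
#'
#' A scale is flagged when its score strictly exceeds the cut-off
#' (9.5 nausea, 15.2 oculomotor, 0 disorientation, 15 total severity).
#' The strict inequality matters: the disorientation cut-off of 0 means
#' "any disorientation symptom at all", and a score exactly at a cut-off
#' is not flagged.
#'
#' @param scores An [ssq_scores] object.
#' @param cutoffs Named numeric vector of cut-offs.
#' @return Named logical vector over the four scales.
#' @export
flag_cutoffs <- function(scores,
                         cutoffs = c(nausea = 9.5, oculomotor = 15.2,
                                     disorientation = 0, total = 15)) {
  stopifnot(inherits(scores, "ssq_scores"))
  vals <- c(nausea = scores$nausea, oculomotor = scores$oculomotor,
            disorientation = scores$disorientation, total = scores$total)
  vals > cutoffs[names(vals)]
}

#' Simulate mild SSQ responses for a synthetic cohort
#'
#' Draws each item independently from a distribution concentrated on
#' "none"/"slight", emulating the minimal-symptom profile a well
#' tolerated VR session produces.
#'
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param item_probs Probabilities of ratings 0-3 per item.
#' @return data.frame, one row per respondent, 16 item columns.
#' @export
simulate_ssq_responses <- function(n, seed = 1,
                                   item_probs = c(0.55, 0.25, 0.15, 0.05)) {
  stopifnot(n >= 1, length(item_probs) == 4)
  items <- rownames(ssq_loadings())
  withr::with_seed(seed, {
    m <- matrix(sample(0:3, n * 16, replace = TRUE, prob = item_probs),
                nrow = n, dimnames = list(NULL, items))
    as.data.frame(m)
  })
}
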