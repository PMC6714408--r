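#' DAS28-ESR disease activity score
#'
#' `0.56*sqrt(TJC28) + 0.28*sqrt(SJC28) + 0.70*ln(ESR) + 0.014*GH`, the
#' four-variable disease activity score over 28 joints with erythrocyte
#' sedimentation rate. Strictly increasing in each component.
#'
#' @param tjc28 tender-joint count over 28 joints, 0--28.
#' @param sjc28 swollen-joint count over 28 joints, 0--28.
#' @param esr erythrocyte sedimentation rate in mm/h, >= 1 (its log is
#'   taken).
#' @param gh general health visual-analogue scale, 0--100 mm.
#' @return DAS28-ESR score (vectorized).
#' @examples
#' das28_esr(10, 8, 30, 50)  # 5.644
#' @export
das28_esr <- function(tjc28, sjc28, esr, gh) {
  check_range(tjc28, 0, 28, "tjc28")
  check_range(sjc28, 0, 28, "sjc28")
  if (any(esr < 1)) stop("esr must be >= 1 (log is taken)")
  check_range(gh, 0, 100, "gh")
  0.56 * sqrt(tjc28) + 0.28 * sqrt(sjc28) + 0.70 * log(esr) + 0.014 * gh
}

#' Clinical disease activity index (CDAI)
#'
#' Plain sum of the joint counts and the two global assessments, without an
#' acute-phase reactant; range 0--76.
#'
#' @param tjc28,sjc28 joint counts, 0--28 each.
#' @param ptga patient global assessment, 0--10.
#' @param phga physician global assessment, 0--10.
#' @return CDAI score (vectorized).
#' @export
cdai <- function(tjc28, sjc28, ptga, phga) {
  check_range(tjc28, 0, 28, "tjc28")
  check_range(sjc28, 0, 28, "sjc28")
  check_range(ptga, 0, 10, "ptga")
  check_range(phga, 0, 10, "phga")
  tjc28 + sjc28 + ptga + phga
}

check_range <- function(x, lo, hi, name) {
  if (any(is.na(x)) || any(x < lo | x > hi))
    stop(sprintf("%s must be in [%g, %g]", name, lo, hi))
  invisible(x)
}

#' EULAR response classification from baseline and attained DAS28
#'
#' Three-level response from the improvement `delta = baseline - month6`
#' and the attained (month-6) DAS28:
#' * `good`: delta > 1.2 and attained <= 3.2;
#' * `none`: delta <= 0.6, or 0.6 < delta <= 1.2 with attained > 5.1;
#' * `moderate`: everything else.
#'
#' @param das28_baseline,das28_month6 DAS28 scores (>= 0), vectorized.
#' @return character vector in `c("good", "moderate", "none")`.
#' @examples
#' eular_response(6.0, 2.9)  # "good"
#' eular_response(4.0, 3.5)  # "none"
#' @export
eular_response <- function(das28_baseline, das28_month6) {
  if (any(das28_baseline < 0) || any(das28_month6 < 0))
    stop("DAS28 scores must be >= 0")
  # guard the decision boundaries against floating-point residue in the
  # subtraction (e.g. 4.4 - 3.2 > 1.2 by 2e-16)
  delta <- round(das28_baseline - das28_month6, 9)
  out <- rep("moderate", length(delta))
  out[delta > 1.2 & das28_month6 <= 3.2] <- "good"
  out[delta <= 0.6 | (delta <= 1.2 & das28_month6 > 5.1)] <- "none"
  out
}

#' Build per-patient response labels from baseline and month-6 visits
#'
#' Computes DAS28-ESR and CDAI at both visits, their changes
#' (`delta = baseline - month6`, so improvement is positive), the EULAR
#' class, and the binary responder flag (good or moderate). Samples missing
#' either visit are skipped with a warning and listed in the `exclusions`
#' attribute; duplicated visits are an error.
#'
#' @param visits data.frame with columns `sample_id`,
#'   `visit` (`"baseline"` or `"month6"`), `tjc28`, `sjc28`, `esr`, `gh`,
#'   `ptga`, `phga`.
#' @return data.frame with one row per complete sample: `sample_id`,
#'   `das28_baseline`, `das28_month6`, `delta_das28`, `cdai_baseline`,
#'   `cdai_month6`, `delta_cdai`, `eular_class`, `is_responder`.
#' @export
build_response_labels <- function(visits) {
  need <- c("sample_id", "visit", "tjc28", "sjc28", "esr", "gh", "ptga", "phga")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visits is missing columns: ", paste(miss, collapse = ", "))
  if (!all(visits$visit %in% c("baseline", "month6")))
    stop("visit must be 'baseline' or 'month6'")
  if (anyDuplicated(visits[, c("sample_id", "visit")]))
    stop("duplicated (sample_id, visit) rows")

  b <- visits[visits$visit == "baseline", ]
  m <- visits[visits$visit == "month6", ]
  complete <- intersect(b$sample_id, m$sample_id)
  skipped <- setdiff(unique(visits$sample_id), complete)
  if (length(skipped))
    warning(sprintf("%d sample(s) missing a visit were skipped: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  b <- b[match(complete, b$sample_id), ]
  m <- m[match(complete, m$sample_id), ]

  das_b <- das28_esr(b$tjc28, b$sjc28, b$esr, b$gh)
  das_m <- das28_esr(m$tjc28, m$sjc28, m$esr, m$gh)
  cdai_b <- cdai(b$tjc28, b$sjc28, b$ptga, b$phga)
  cdai_m <- cdai(m$tjc28, m$sjc28, m$ptga, m$phga)
  cls <- eular_response(das_b, das_m)
  out <- data.frame(sample_id = complete,
                    das28_baseline = das_b, das28_month6 = das_m,
                    delta_das28 = das_b - das_m,
                    cdai_baseline = cdai_b, cdai_month6 = cdai_m,
                    delta_cdai = cdai_b - cdai_m,
                    eular_class = cls,
                    is_responder = cls != "none",
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- skipped
  out
}
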