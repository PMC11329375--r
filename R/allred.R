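#' Modified Allred proportion score
#'
#' Bins the fraction of positively stained carcinoma cells into the
#' 0-5 proportion score: none 0; below 1/100 scores 1; 1/100 to 1/10
#' scores 2; above 1/10 to 1/3 scores 3; above 1/3 to 2/3 scores 4;
#' above 2/3 scores 5.  The boundary convention is declared, not implied
#' by the published bin labels: the extreme bins are strict (`< 1/100`,
#' `> 2/3`), so exactly 1/100 scores 2, and each interior boundary
#' belongs to the bin it closes (exactly 1/10 scores 2, exactly 1/3
#' scores 3, exactly 2/3 scores 4).
#'
#' @param fraction Fraction(s) of positive cells in `[0, 1]`.
#' @return Integer score(s) 0-5.
#' @examples
#' proportion_score(c(0, 0.005, 1/3, 0.5, 0.9))
#' @export
proportion_score <- function(fraction) {
  if (!is.numeric(fraction) || any(!is.finite(fraction)) ||
      any(fraction < 0) || any(fraction > 1)) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  score <- 1L + (fraction >= 1 / 100) + (fraction > 1 / 10) +
    (fraction > 1 / 3) + (fraction > 2 / 3)
  score[fraction == 0] <- 0L
  as.integer(score)
}

#' Modified Allred total score and low/high category
#'
#' Adds the 0-5 proportion score to the 0-3 staining intensity score
#' (none 0, weak 1, intermediate 2, strong 3) for a 0-8 total;
#' totals of 0-3 are classed `low` and 4-8 `high`.
#'
#' @param fraction Fraction(s) of positive cells in `[0, 1]`; a zero
#'   fraction requires zero intensity.
#' @param intensity Integer intensity score(s) 0-3.
#' @return data.frame with `proportion_fraction`, `proportion_score`,
#'   `intensity_score`, `total`, `category`.
#' @examples
#' allred_total(0.5, 2)  # total 6, high
#' @export
allred_total <- function(fraction, intensity) {
  ps <- proportion_score(fraction)
  if (!is.numeric(intensity) || any(intensity != as.integer(intensity)) ||
      any(intensity < 0) || any(intensity > 3)) {
    stop("`intensity` must be an integer score 0-3", call. = FALSE)
  }
  n <- max(length(fraction), length(intensity))
  fraction <- rep_len(fraction, n)
  ps <- rep_len(ps, n)
  intensity <- rep_len(as.integer(intensity), n)
  if (any(fraction == 0 & intensity > 0)) {
    stop("inconsistent scores: zero positive fraction with nonzero intensity",
         call. = FALSE)
  }
  total <- ps + intensity
  data.frame(proportion_fraction = fraction,
             proportion_score = ps,
             intensity_score = intensity,
             total = total,
             category = ifelse(total <= 3, "low", "high"))
}

#' Score a table of immunostained cases
#'
#' @param cases data.frame with columns `case_id`, `fraction`,
#'   `intensity`.
#' @return The input with `proportion_score`, `intensity_score`, `total`
#'   and `category` columns appended.
#' @examples
#' cases <- read.csv(system.file("extdata", "synthetic_allred_cases.csv",
#'                               package = "navloop"))
#' allred_score(cases)
#' @export
allred_score <- function(cases) {
  need <- c("case_id", "fraction", "intensity")
  if (!all(need %in% names(cases))) {
    stop("`cases` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sc <- allred_total(cases$fraction, cases$intensity)
  cbind(cases["case_id"], sc)
}
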