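# Health-workforce weighting from national staffing standards, per-district
# availability terms, and the combined healthcare-equity index.

#' National staffing standard (persons per worker)
#'
#' The Indonesian recommended coverage standards: one physician per 2,500
#' residents, one midwife per 1,000, one nurse per 855.
#'
#' @param persons_per_physician,persons_per_midwife,persons_per_nurse
#'   positive reals.
#' @return a `staffing_standard` list.
#' @export
staffing_standard <- function(persons_per_physician = 2500,
                              persons_per_midwife = 1000,
                              persons_per_nurse = 855) {
  if (persons_per_physician <= 0 || persons_per_midwife <= 0 ||
      persons_per_nurse <= 0) {
    stop("staffing standard ratios must be > 0")
  }
  structure(list(persons_per_physician = persons_per_physician,
                 persons_per_midwife = persons_per_midwife,
                 persons_per_nurse = persons_per_nurse),
            class = "staffing_standard")
}

#' Worker weights from a staffing standard
#'
#' Each cadre's weight is its persons-per-worker standard normalised to the
#' nurse standard: w_k = persons_per_k / persons_per_nurse. Under the
#' national standard this gives 2.92 (physician), 1.17 (midwife), 1 (nurse)
#' at 2-decimal reporting precision.
#'
#' @param standard a [staffing_standard()].
#' @param digits reporting rounding (default 2; use `NA` for full precision).
#' @return named vector `c(physician, midwife, nurse)`.
#' @export
standard_weights <- function(standard = staffing_standard(), digits = 2) {
  w <- c(physician = standard$persons_per_physician / standard$persons_per_nurse,
         midwife = standard$persons_per_midwife / standard$persons_per_nurse,
         nurse = 1)
  if (!is.na(digits)) w <- round_half_up(w, digits)
  w
}

#' Weighted workforce of a facility
#'
#' mu contribution: physicians * w_physician + midwives * w_midwife +
#' nurses * w_nurse.
#'
#' @param physicians,midwives,nurses non-negative counts (vectorised).
#' @param weights named weight vector from [standard_weights()].
#' @return weighted worker total(s).
#' @export
weighted_workforce <- function(physicians, midwives, nurses,
                               weights = standard_weights()) {
  if (any(c(physicians, midwives, nurses) < 0)) {
    stop("staff counts must be non-negative")
  }
  physicians * weights[["physician"]] + midwives * weights[["midwife"]] +
    nurses * weights[["nurse"]]
}

#' Workforce availability terms of a district
#'
#' x: weighted puskesmas workers per 1,000 population; y: the same over the
#' district's hospitals. A district with no facility of a type has
#' availability 0 for that type.
#'
#' @param population district census total (> 0).
#' @param facilities facility table rows of the district.
#' @param weights worker weights.
#' @return named vector `c(x, y)` plus attributes `mu_puskesmas`,
#'   `mu_hospital`, `a` (puskesmas count), `b` (hospital count).
#' @export
availability_terms <- function(population, facilities,
                               weights = standard_weights()) {
  if (population <= 0) stop("population must be > 0")
  mu_of <- function(kind) {
    f <- facilities[facilities$kind == kind, , drop = FALSE]
    if (!nrow(f)) return(0)
    sum(weighted_workforce(f$physicians, f$midwives, f$nurses, weights))
  }
  mu_p <- mu_of("puskesmas")
  mu_h <- mu_of("hospital")
  out <- c(x = 1000 * mu_p / population, y = 1000 * mu_h / population)
  attr(out, "mu_puskesmas") <- mu_p
  attr(out, "mu_hospital") <- mu_h
  attr(out, "a") <- sum(facilities$kind == "puskesmas")
  attr(out, "b") <- sum(facilities$kind == "hospital")
  out
}

#' District healthcare-equity index
#'
#' Combines the population-weighted total travel distance z with the
#' workforce availability terms. The default `"availability"` form is
#' equity = z / mean(x, y): strictly increasing in distance, strictly
#' decreasing in either availability term; low is excellent, high is severe.
#' The `"ratio"` form is the reciprocal-availability reading,
#' z * mean(1/x, 1/y) (terms with zero availability are dropped from the
#' mean in that form).
#'
#' @param z weighted total distance (km, >= 0).
#' @param x,y availability terms (weighted workers per 1,000 population).
#' @param form `"availability"` (default) or `"ratio"`.
#' @return the equity value (low = excellent).
#' @export
equity_index <- function(z, x, y, form = c("availability", "ratio")) {
  form <- match.arg(form)
  if (z < 0) stop("z must be >= 0")
  if (x + y <= 0) stop("no workforce in district: x = y = 0")
  if (form == "availability") {
    z / mean(c(x, y))
  } else {
    inv <- 1 / c(x, y)
    z * mean(inv[is.finite(inv)])
  }
}

#' Rank districts by equity
#'
#' Ascending equity value: rank 1 is the lowest value (best equity). Ties
#' break alphabetically by district name.
#'
#' @param scores data frame with `district_id`, `name`, `equity`.
#' @return the data frame sorted, with a `rank` column added.
#' @export
rank_districts <- function(scores) {
  if (!nrow(scores)) stop("no equity scores")
  out <- scores[order(scores$equity, scores$name), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
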