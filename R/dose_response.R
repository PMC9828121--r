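#' Define a dose-response endpoint from a standard regulatory test
#'
#' Encapsulates one laboratory endpoint — median lethal dose (LD50), slope,
#' test duration and exposure regime — as reported by the standard honeybee
#' tests: acute oral (single dose, observed 48 h), acute contact (single
#' dose, 48 h), chronic oral (daily dose over 10 days) and larval
#' (repeated daily dose, mortality read at 7 days, or at 22 days when the
#' mode of action expresses in the pupal stage).
#'
#' For `single_dose` endpoints `ld50` is a total dose in ug/bee; for
#' `repeated_daily` endpoints it is a daily dose (ug/bee/day or
#' ug/larva/day) held constant over the test.
#'
#' @param endpoint One of `"acute_oral"`, `"chronic_oral"`, `"contact"`,
#'   `"larval"`.
#' @param ld50 Median lethal dose, ug/bee (ug/larva for larval tests); > 0.
#' @param slope Dimensionless log-logistic slope; > 0.
#' @param test_duration_days Test duration in days (acute 48 h -> 2,
#'   chronic -> 10, larval -> 7 or 22).
#' @param regime `"single_dose"` or `"repeated_daily"`.
#' @return An object of class `"dose_response"`.
#' @examples
#' dr <- dose_response("acute_oral", ld50 = 0.1, slope = 2)
#' dose_response_mortality(0.1, dr) # 0.5 by definition of the LD50
#' @export
dose_response <- function(endpoint, ld50, slope,
                          test_duration_days = switch(endpoint,
                            acute_oral = 2, contact = 2,
                            chronic_oral = 10, larval = 7),
                          regime = switch(endpoint,
                            acute_oral = "single_dose",
                            contact = "single_dose",
                            "repeated_daily")) {
  endpoint <- match.arg(endpoint,
    c("acute_oral", "chronic_oral", "contact", "larval"))
  regime <- match.arg(regime, c("single_dose", "repeated_daily"))
  stopifnot(is.numeric(ld50), length(ld50) == 1, ld50 > 0,
            is.numeric(slope), length(slope) == 1, slope > 0,
            test_duration_days >= 1)
  structure(
    list(endpoint = endpoint, ld50 = ld50, slope = slope,
         test_duration_days = as.integer(test_duration_days),
         regime = regime),
    class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %s: LD50 = %g ug, slope = %g, %d d (%s)\n",
              x$endpoint, x$ld50, x$slope, x$test_duration_days, x$regime))
  invisible(x)
}

#' Mortality fraction over the test duration at a given dose
#'
#' Two-parameter log-logistic dose-response:
#' \deqn{M(d) = \frac{1}{1 + (LD_{50}/d)^{slope}}, \qquad M(0) = 0.}
#' Returns the mortality fraction over the endpoint's full test duration.
#'
#' @param dose_ug Dose in ug/bee (single-dose endpoints) or ug/bee/day
#'   (repeated-daily endpoints). Vectorised; must be >= 0.
#' @param dr A [dose_response()] object.
#' @return Mortality fraction(s) in `[0, 1)`.
#' @export
dose_response_mortality <- function(dose_ug, dr) {
  stopifnot(inherits(dr, "dose_response"), all(dose_ug >= 0))
  m <- ifelse(dose_ug > 0, 1 / (1 + (dr$ld50 / dose_ug)^dr$slope), 0)
  as.numeric(m)
}

#' Scale a test-duration mortality to a constant daily mortality
#'
#' Assumes a constant daily hazard over the test: a mortality fraction
#' `M_T` observed after `T` days corresponds to the daily mortality
#' \deqn{q = 1 - (1 - M_T)^{1/T}.}
#' Compounding `q` over `T` days recovers `M_T` exactly.
#'
#' @param m_total Mortality fraction over the test duration, in `[0, 1]`.
#' @param t_days Test duration in days, >= 1.
#' @return Daily mortality fraction(s).
#' @examples
#' to_daily_mortality(0.5, 10) # ~0.0670
#' @export
to_daily_mortality <- function(m_total, t_days) {
  stopifnot(all(m_total >= 0), all(m_total <= 1), all(t_days >= 1))
  ifelse(m_total >= 1, 1, 1 - (1 - m_total)^(1 / t_days))
}

# Daily mortality implied by one endpoint at the day's dose.
# The acute 48-h relationship is applied to the daily summed dose as the
# mortality consequence of that single day's intake (no 2-day split, which
# would double-count a single-dose endpoint); repeated-daily endpoints are
# scaled through the constant-hazard assumption.
endpoint_daily_mortality <- function(dose_ug, dr) {
  m <- dose_response_mortality(dose_ug, dr)
  if (dr$regime == "single_dose") m
  else to_daily_mortality(m, dr$test_duration_days)
}

#' Combined daily mortality for adult bees
#'
#' Oral mortality takes the most conservative of the acute-oral and
#' chronic-oral endpoints, evaluated pointwise at the day's summed oral
#' dose (so the larger daily mortality always wins, whichever curve it
#' comes from). Contact mortality applies the contact endpoint to the
#' day's contact dose (nonzero only on application days, foragers only).
#' The three pathways compose as independent hazards:
#' \deqn{1 - q = (1 - q_{oral})(1 - q_{contact})(1 - q_{background}).}
#'
#' Missing endpoints contribute zero mortality for their pathway.
#'
#' @param oral_dose_ug Summed oral dose for the day, ug/bee.
#' @param contact_dose_ug Contact dose for the day, ug/bee.
#' @param profile A [pesticide_profile()] (its `dose_responses` are used),
#'   or `NULL` for no pesticide.
#' @param background Background daily mortality to fold in (default 0).
#' @return Combined daily mortality fraction.
#' @export
adult_daily_mortality <- function(oral_dose_ug, contact_dose_ug,
                                  profile, background = 0) {
  q_oral <- oral_mortality_q(oral_dose_ug, profile)
  q_contact <- contact_mortality_q(contact_dose_ug, profile)
  1 - (1 - q_oral) * (1 - q_contact) * (1 - background)
}

# max over available oral endpoints ("preference is given to the most
# conservative dose-response relationship")
oral_mortality_q <- function(oral_dose_ug, profile) {
  if (is.null(profile)) return(rep(0, length(oral_dose_ug)))
  q <- rep(0, length(oral_dose_ug))
  for (ep in c("acute_oral", "chronic_oral")) {
    dr <- profile$dose_responses[[ep]]
    if (!is.null(dr)) q <- pmax(q, endpoint_daily_mortality(oral_dose_ug, dr))
  }
  q
}

contact_mortality_q <- function(contact_dose_ug, profile) {
  if (is.null(profile)) return(rep(0, length(contact_dose_ug)))
  dr <- profile$dose_responses[["contact"]]
  if (is.null(dr)) return(rep(0, length(contact_dose_ug)))
  endpoint_daily_mortality(contact_dose_ug, dr)
}

# Larval endpoint, daily mortality at the day's dose (7-d endpoint), or the
# per-pupal-day hazard that spreads the 22-d endpoint's total mortality
# uniformly over the pupal stage.
larval_mortality_q <- function(dose_ug, profile) {
  if (is.null(profile)) return(rep(0, length(dose_ug)))
  dr <- profile$dose_responses[["larval"]]
  if (is.null(dr)) return(rep(0, length(dose_ug)))
  endpoint_daily_mortality(dose_ug, dr)
}
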