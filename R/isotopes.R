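#' Deuterium excess
#'
#' \code{d-excess = d2H - 8 * d18O} (the standard Dansgaard definition),
#' sensitive to vapor source and evaporative fractionation. Samples on the
#' global meteoric water line (\code{d2H = 8 d18O + 10}) have d-excess 10.
#'
#' @param d2H,d18O stable isotope ratios, permil VSMOW (vectorized).
#' @return d-excess, permil.
#' @examples
#' dExcess(-53.9, -8.0)  # 10.1
#' @export
dExcess <- function(d2H, d18O) {
  if (any(!is.finite(d2H)) || any(!is.finite(d18O)))
    stop("isotope values must be finite")
  d2H - 8 * d18O
}

#' Two-component mixing fraction of event ("new") water
#'
#' Tracer mass balance between an old-water endmember (pre-event streamflow)
#' and a new-water endmember (event precipitation):
#' \code{f_new = (c_stream - c_old) / (c_new - c_old)}. With noisy
#' endmembers the raw fraction can leave [0, 1]; such values are clipped
#' with a warning reporting the raw range. Endmembers closer together than
#' \code{min_separation} make the mixing model unidentifiable and are an
#' error.
#'
#' @param c_stream stream tracer value(s) (e.g. d2H, permil).
#' @param c_old,c_new endmember tracer values.
#' @param min_separation minimum |c_old - c_new| (default 1, suited to d2H
#'   in permil).
#' @return event-water fraction(s) in [0, 1].
#' @examples
#' twoComponentFraction(-52.1, -53.9, -38.7)  # 1.8 / 15.2
#' @export
twoComponentFraction <- function(c_stream, c_old, c_new, min_separation = 1) {
  if (abs(c_old - c_new) < min_separation)
    stop("endmember separation |c_old - c_new| below ", min_separation,
         ": mixing model unidentifiable")
  f_raw <- (c_stream - c_old) / (c_new - c_old)
  out <- pmin(1, pmax(0, f_raw))
  clipped <- f_raw < 0 | f_raw > 1
  if (any(clipped))
    warning(sum(clipped), " mixing fraction(s) outside [0, 1] clipped (raw range ",
            sprintf("%.4f .. %.4f", min(f_raw), max(f_raw)), ")")
  out
}

#' Isotopic hydrograph separation over the sampled record
#'
#' Applies \code{\link{twoComponentFraction}} per day. The old-water
#' endmember defaults to the mean pre-event stream tracer value; the
#' new-water endmember is the event precipitation value (precipitation
#' -weighted mean if weights are supplied, plain mean otherwise).
#'
#' @param isotopes data.frame with \code{date} and the tracer column.
#' @param discharge named daily discharge [CMS] keyed by ISO date.
#' @param delta_new new-water (precipitation) endmember value(s); averaged
#'   with \code{precip_weights} when given as a vector.
#' @param preevent_dates dates defining the old-water endmember (default:
#'   first four sample days).
#' @param tracer column of \code{isotopes} to use (default \code{"d2H"}).
#' @param precip_weights optional weights for averaging \code{delta_new}.
#' @param min_separation as \code{\link{twoComponentFraction}}.
#' @return data.frame with \code{date}, \code{f_new_raw}, \code{f_new},
#'   \code{f_old}, \code{event_water_cms}; endmembers recorded as
#'   attributes \code{c_old}, \code{c_new}.
#' @export
hydrographSeparation <- function(isotopes, discharge, delta_new,
                                 preevent_dates = NULL, tracer = "d2H",
                                 precip_weights = NULL, min_separation = 1) {
  if (!tracer %in% colnames(isotopes))
    stop("tracer column '", tracer, "' not in isotope series")
  dates <- as.character(isotopes$date)
  pre <- .resolve_dates(dates, preevent_dates)
  c_old <- mean(isotopes[[tracer]][dates %in% pre])
  c_new <- if (is.null(precip_weights)) mean(delta_new)
           else sum(delta_new * precip_weights) / sum(precip_weights)
  f_raw <- (isotopes[[tracer]] - c_old) / (c_new - c_old)
  if (abs(c_old - c_new) < min_separation)
    stop("endmember separation below ", min_separation)
  f <- suppressWarnings(twoComponentFraction(isotopes[[tracer]], c_old, c_new,
                                             min_separation))
  if (any(f != f_raw))
    warning(sum(f != f_raw), " daily mixing fraction(s) clipped to [0, 1]")
  q <- if (!is.null(names(discharge))) discharge[dates] else discharge
  out <- data.frame(date = isotopes$date, f_new_raw = f_raw, f_new = f,
                    f_old = 1 - f, event_water_cms = f * as.numeric(q),
                    row.names = NULL)
  attr(out, "c_old") <- c_old
  attr(out, "c_new") <- c_new
  out
}

#' Summarize the event flow response
#'
#' Pre-event mean discharge, the peak discharge and its date, the percent
#' increase \code{100 (Q_peak - Q_pre) / Q_pre}, and -- when a mixing table
#' is supplied -- the event-water fraction and discharge on the peak day.
#'
#' @param hydro data.frame with \code{date} and \code{discharge_cms}, or a
#'   named discharge vector keyed by ISO date.
#' @param mixing optional result of \code{\link{hydrographSeparation}}.
#' @param preevent_dates baseline days (default: first four).
#' @return list with \code{q_pre_cms}, \code{q_peak_cms}, \code{peak_date},
#'   \code{percent_increase}, and (with \code{mixing})
#'   \code{peak_event_water_fraction}, \code{peak_event_water_cms}.
#' @export
eventResponseSummary <- function(hydro, mixing = NULL, preevent_dates = NULL) {
  if (is.data.frame(hydro)) {
    q <- stats::setNames(hydro$discharge_cms, as.character(hydro$date))
  } else q <- hydro
  dates <- names(q)
  pre <- .resolve_dates(dates, preevent_dates)
  q_pre <- mean(q[pre])
  peak <- which.max(q)
  out <- list(q_pre_cms = q_pre,
              q_peak_cms = unname(q[peak]),
              peak_date = dates[peak],
              percent_increase = 100 * (unname(q[peak]) - q_pre) / q_pre)
  if (!is.null(mixing)) {
    i <- match(dates[peak], as.character(mixing$date))
    if (!is.na(i)) {
      out$peak_event_water_fraction <- mixing$f_new[i]
      out$peak_event_water_cms <- mixing$f_new[i] * out$q_peak_cms
    }
  }
  out
}
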