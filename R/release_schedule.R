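#' Implant release schedule
#'
#' Zero-order, time-varying release of drug from the subdermal implant,
#' given as (time, rate) knots. The default table is the reported release
#' profile of a 150 mg levonorgestrel implant: 100 ug/day at one month
#' post-insertion declining to 40 ug/day at one year, 30 ug/day at three
#' years and 25 ug/day at five years, with interpolated intermediate rows.
#' Rates are amounts reaching the systemic circulation, so implant input
#' enters the central compartment directly with no first-pass loss.
#'
#' @param knots Data frame or matrix with columns `month` (strictly
#'   increasing, >= 0) and `rate_ug_day` (strictly positive).
#' @param scale Dimensionless multiplier applied to every rate; `scale = 2`
#'   represents the doubled 300 mg implant (four rods instead of two).
#' @return An object of class `release_schedule`.
#' @export
release_schedule <- function(knots = default_release_knots(), scale = 1) {
  knots <- as.data.frame(knots)
  stopifnot(ncol(knots) == 2, nrow(knots) >= 1, scale > 0)
  names(knots) <- c("month", "rate_ug_day")
  stopifnot(all(knots$month >= 0), all(diff(knots$month) > 0),
            all(knots$rate_ug_day > 0))
  knots$rate_ug_day <- knots$rate_ug_day * scale
  structure(list(knots = knots, extrapolation = "flat"),
            class = "release_schedule")
}

#' Default implant release-rate table
#'
#' @return Data frame of (month, ug/day) knots:
#'   (1,100), (3,89), (6,73), (12,40), (24,35), (36,30), (60,25).
#' @export
default_release_knots <- function() {
  data.frame(month = c(1, 3, 6, 12, 24, 36, 60),
             rate_ug_day = c(100, 89, 73, 40, 35, 30, 25))
}

#' Interpolated implant release rate
#'
#' Piecewise-linear interpolation between the schedule knots, constant at
#' the first knot's rate before it and at the last knot's rate after it.
#'
#' @param schedule A [release_schedule()].
#' @param t_months Time(s) post-placement in months; must be >= 0.
#' @return Release rate(s), ug/day.
#' @examples
#' sch <- release_schedule()
#' release_rate(sch, 12)   # 40
#' release_rate(sch, 4.5)  # 81, midway between (3, 89) and (6, 73)
#' @export
release_rate <- function(schedule, t_months) {
  stopifnot(inherits(schedule, "release_schedule"))
  if (any(t_months < 0)) {
    stop("release_rate(): time before implant placement (t < 0 months) is not defined")
  }
  stats::approx(schedule$knots$month, schedule$knots$rate_ug_day,
                xout = t_months, method = "linear", rule = 2)$y
}

#' @export
print.release_schedule <- function(x, ...) {
  cat("<release_schedule> piecewise-linear, flat extrapolation\n")
  print(x$knots, row.names = FALSE)
  invisible(x)
}

#' Dosing event
#'
#' One administration pattern for the simulator: a subdermal implant (whose
#' input is its release schedule), repeated oral doses, or an intravenous
#' bolus/infusion.
#'
#' @param route One of `"implant"`, `"oral"`, `"iv_infusion"`.
#' @param amount Dose, mg: total implant load (150 or 300), or mg per
#'   administration for oral/IV.
#' @param schedule For `route = "implant"`: a [release_schedule()]. Ignored
#'   otherwise.
#' @param start Time of (first) administration, h (oral/IV). Default 0.
#' @param interval Inter-dose interval, h, for repeated oral dosing.
#' @param n_doses Number of oral administrations (default 1).
#' @param duration Infusion duration, h (`iv_infusion`); 0 means bolus.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(route = c("implant", "oral", "iv_infusion"),
                       amount,
                       schedule = NULL,
                       start = 0, interval = 24, n_doses = 1,
                       duration = 0) {
  route <- match.arg(route)
  stopifnot(amount > 0, start >= 0, n_doses >= 1, duration >= 0)
  if (route == "implant") {
    if (is.null(schedule)) {
      # default table is for the standard 150 mg implant; scale linearly
      schedule <- release_schedule(scale = amount / 150)
    }
    stopifnot(inherits(schedule, "release_schedule"))
  }
  if (n_doses > 1) stopifnot(interval > 0)
  structure(list(route = route, amount = amount, schedule = schedule,
                 start = start, interval = interval, n_doses = n_doses,
                 duration = duration),
            class = "dose_event")
}

#' @export
print.dose_event <- function(x, ...) {
  cat(sprintf("<dose_event> %s, %g mg", x$route, x$amount))
  if (x$route == "oral" && x$n_doses > 1)
    cat(sprintf(" x%d q%gh", x$n_doses, x$interval))
  if (x$route == "iv_infusion" && x$duration > 0)
    cat(sprintf(" over %g h", x$duration))
  cat("\n")
  invisible(x)
}
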