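# Composite trapezoid on (times, values); assumes times sorted.
trapezoid <- function(times, values) {
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

as_curve <- function(curve) {
  if (is.data.frame(curve)) {
    stopifnot(all(c("time", "mean") %in% names(curve)))
    curve <- curve[order(curve$time), ]
    list(time = curve$time, mean = curve$mean)
  } else {
    stopifnot(is.numeric(curve), !is.null(names(curve)))
    t <- as.numeric(names(curve))
    o <- order(t)
    list(time = t[o], mean = unname(curve[o]))
  }
}

#' Trapezoid area under an induction curve
#'
#' Composite trapezoid of the mean curve over `window`; window endpoints
#' between samples are linearly interpolated. AUC is additive over adjacent
#' windows.
#'
#' @param curve data frame with `time` and `mean` columns (time units as
#'   declared by the caller), or a named numeric vector (names = times).
#' @param window `(t_start, t_end)` within the observed span; defaults to
#'   the full span.
#' @return area in value x time units.
#' @export
trapezoid_auc <- function(curve, window = NULL) {
  cv <- as_curve(curve)
  if (is.null(window)) window <- range(cv$time)
  if (window[1] < min(cv$time) || window[2] > max(cv$time))
    stop("window outside observed span")
  tt <- sort(unique(c(cv$time[cv$time >= window[1] & cv$time <= window[2]],
                      window)))
  vv <- stats::approx(cv$time, cv$mean, xout = tt)$y
  trapezoid(tt, vv)
}

#' AUC of one curve as a percentage of another
#'
#' @param curveA,curveB induction curves (see [trapezoid_auc()]).
#' @param window integration window applied to both.
#' @return `100 * AUC(A) / AUC(B)`.
#' @export
auc_ratio <- function(curveA, curveB, window = NULL) {
  b <- trapezoid_auc(curveB, window)
  if (b == 0) stop("zero denominator AUC")
  100 * trapezoid_auc(curveA, window) / b
}

#' Peak time and fold induction versus baseline
#'
#' Argmax of the mean curve and its ratio to the t = 0 value; ties resolved
#' to the earliest peak.
#'
#' @param curve induction curve (see [trapezoid_auc()]).
#' @return list with `peak_time` and `fold`.
#' @export
peak_fold_change <- function(curve) {
  cv <- as_curve(curve)
  if (cv$time[1] != 0) stop("curve must include t = 0")
  if (cv$mean[1] <= 0) stop("zero or negative baseline")
  i <- which.max(cv$mean)
  list(peak_time = cv$time[i], fold = cv$mean[i] / cv$mean[1])
}
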