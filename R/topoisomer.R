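#' Discretized topoisomer distributions
#'
#' A covalently closed plasmid population resolves on an agarose/chloroquine
#' gel as a ladder of topoisomers differing by integer apparent linking number
#' (Lk). Relaxation by a topoisomerase leaves an approximately Gaussian
#' distribution of Lk around its thermodynamic mean; `topoisomer_distribution()`
#' builds that distribution on integer support: a Gaussian density evaluated at
#' the integers in `round(mean_lk) +/- half_support` and renormalized to sum
#' to one. `sd = 0` gives a point mass at `round(mean_lk)`.
#'
#' Lk indices here are apparent and relative (the gel does not resolve the
#' sign of supercoiling); index 0 is by convention the topmost band of a
#' ladder, larger indices migrate further down the gel.
#'
#' @param mean_lk Target mean apparent linking number (may be fractional).
#' @param sd Standard deviation of the underlying Gaussian, in linking
#'   numbers; `>= 0`.
#' @param half_support Half-width of the integer support, in linking numbers;
#'   the support should cover at least `4 * sd` around `mean_lk`, otherwise
#'   the distribution is silently truncated.
#' @return An object of class `"topo_dist"`: a list with `lk` (integer
#'   support), `p` (probabilities summing to 1), `mean_lk` (the realized mean
#'   `sum(p * lk)`), and the nominal `target_mean`, `sd`, `half_support` used
#'   to build it.
#' @examples
#' d <- topoisomer_distribution(3, sd = 1, half_support = 4)
#' sum(d$p)      # 1
#' d$mean_lk     # 3
#' @export
topoisomer_distribution <- function(mean_lk, sd, half_support = 4L) {
  if (!is_num1(mean_lk)) stop_tq("topoquant_invalid_parameter", "mean_lk must be a finite number")
  if (!is_num1(sd) || sd < 0) stop_tq("topoquant_invalid_parameter", "sd must be a finite number >= 0")
  if (!is_count(half_support) || half_support < 1) {
    stop_tq("topoquant_invalid_parameter", "half_support must be an integer >= 1")
  }
  center <- round(mean_lk)
  lk <- seq.int(center - half_support, center + half_support)
  if (sd == 0) {
    p <- as.numeric(lk == center)
  } else {
    w <- stats::dnorm(lk, mean = mean_lk, sd = sd)
    if (sum(w) <= 0) stop_tq("topoquant_invalid_parameter", "distribution has no mass on the support")
    p <- w / sum(w)
  }
  structure(
    list(lk = as.integer(lk), p = p, mean_lk = sum(p * lk),
         target_mean = mean_lk, sd = sd, half_support = as.integer(half_support)),
    class = "topo_dist"
  )
}

#' @export
print.topo_dist <- function(x, ...) {
  cat(sprintf("Topoisomer distribution: %d species, Lk in [%d, %d]\n",
              length(x$lk), min(x$lk), max(x$lk)))
  cat(sprintf("  mean Lk = %.4f (target %.4f), sd = %.3f\n",
              x$mean_lk, x$target_mean, x$sd))
  invisible(x)
}

#' Shift a topoisomer distribution through a gyrase time course
#'
#' DNA gyrase activity is defined as the increase in mean apparent Lk per hour
#' relative to the starting topoisomer distribution. This is the forward
#' model: the mean shifts linearly in time at `rate_dlk_per_h`, the spread is
#' unchanged, and the distribution is re-discretized on integer support. Two
#' consecutive half-length steps compose exactly into one full step.
#'
#' @param dist0 Starting [topoisomer_distribution()].
#' @param rate_dlk_per_h Signed rate in delta-Lk per hour (negative =
#'   relaxation).
#' @param hours Incubation time, `>= 0`.
#' @return A `"topo_dist"` with target mean `dist0` target mean `+
#'   rate_dlk_per_h * hours`.
#' @export
simulate_gyrase_timecourse <- function(dist0, rate_dlk_per_h, hours) {
  if (!inherits(dist0, "topo_dist")) stop_tq("topoquant_invalid_parameter", "dist0 must be a topo_dist")
  if (!is_num1(rate_dlk_per_h)) stop_tq("topoquant_invalid_parameter", "rate_dlk_per_h must be a finite number")
  if (!is_num1(hours) || hours < 0) stop_tq("topoquant_invalid_parameter", "hours must be a finite number >= 0")
  topoisomer_distribution(dist0$target_mean + rate_dlk_per_h * hours,
                          sd = dist0$sd, half_support = dist0$half_support)
}
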