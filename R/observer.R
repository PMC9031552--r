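# Simulated patient: converts stimulus states into visibility and timed
# button events.

#' Simulated observer parameters
#'
#' The response rule is a hard containment criterion: the dot is reported
#' invisible exactly when the fraction of its disc lying in an absolute
#' region reaches `containment_threshold` (default 1: only full
#' containment extinguishes it). Relative regions dim the dot but never
#' extinguish it, so they generate no off/on events. Reaction time is
#' Gaussian (mean/sd, truncated at zero); attentional lapses delete an
#' off event together with its paired on event; false alarms insert brief
#' spurious pairs. All defaults are zero, making the whole pipeline
#' deterministic and seed-free.
#'
#' @param containment_threshold Fraction in `(0, 1]` of the disc that must
#'   lie in absolute scotoma for the dot to disappear.
#' @param latency_mean_s,latency_sd_s Reaction-time model in seconds.
#' @param lapse_rate Probability of missing (not reporting) a disappearance.
#' @param false_alarm_rate Per-frame probability of a spurious report.
#' @param rng_seed Integer seed for the stochastic components.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(containment_threshold = 1,
                            latency_mean_s = 0, latency_sd_s = 0,
                            lapse_rate = 0, false_alarm_rate = 0,
                            rng_seed = 1L) {
  if (containment_threshold <= 0 || containment_threshold > 1) {
    stop("containment_threshold must lie in (0, 1]")
  }
  if (latency_mean_s < 0 || latency_sd_s < 0) {
    stop("latency parameters must be non-negative")
  }
  if (lapse_rate < 0 || lapse_rate >= 1 ||
      false_alarm_rate < 0 || false_alarm_rate >= 1) {
    stop("rates must lie in [0, 1)")
  }
  structure(list(containment_threshold = containment_threshold,
                 latency_mean_s = latency_mean_s,
                 latency_sd_s = latency_sd_s,
                 lapse_rate = lapse_rate,
                 false_alarm_rate = false_alarm_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "observer_params")
}

observer_is_stochastic <- function(obs) {
  obs$latency_sd_s > 0 || obs$lapse_rate > 0 || obs$false_alarm_rate > 0
}

#' Is the dot visible to the observer?
#'
#' The dot is invisible iff the absolute-coverage fraction of its disc
#' reaches the observer's containment threshold. With the default
#' threshold of 1, a 0.31-degree dot centred in a 0.35-degree absolute
#' band disappears while a 0.43-degree stimulus in the same band does not.
#'
#' @param field A [visual_field()].
#' @param obs An [observer_params()].
#' @param center Disc centre(s): `c(x_deg, y_deg)` or an n x 2 matrix.
#' @param diameter_deg Dot angular diameter(s) in degrees.
#' @return Logical vector: `TRUE` where visible.
#' @export
stimulus_visible <- function(field, obs, center, diameter_deg) {
  center <- as_field_points(center)
  fr <- disc_coverage_fractions(field, center[, 1], center[, 2],
                                diameter_deg, "absolute")
  fr < obs$containment_threshold - 1e-12
}

#' Convert a visibility timeline into timed off/on events
#'
#' Emits an `"off"` event at every visible-to-invisible transition and an
#' `"on"` event at every invisible-to-visible transition (an initially
#' invisible timeline opens with an off at its first frame). Each event is
#' delayed by a latency draw; lapses delete off/on pairs together, so the
#' stream stays well-formed; false alarms insert one-frame spurious pairs
#' in visible stretches. With all noise parameters zero the observer is an
#' exact change-point detector and no random numbers are consumed.
#'
#' @param visible Logical visibility per frame.
#' @param t Frame times in seconds (same length as `visible`).
#' @param obs An [observer_params()].
#' @param seed Seed for the stochastic components; `NA` to draw from the
#'   current RNG stream (used internally by the exam engine, which seeds
#'   once per exam). Defaults to `obs$rng_seed`.
#' @return A data frame with columns `frame`, `event` (`"off"`/`"on"`),
#'   `latency_s` and `t_response_s`.
#' @export
respond <- function(visible, t, obs = observer_params(), seed = obs$rng_seed) {
  stopifnot(length(visible) == length(t))
  n <- length(visible)
  if (n == 0) return(empty_response_df())
  use_rng <- observer_is_stochastic(obs)
  if (use_rng && !is.na(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  off_fr <- which(c(!visible[1], visible[-n] & !visible[-1]))
  on_fr <- which(c(FALSE, !visible[-n] & visible[-1]))
  # lapses: drop an off together with the on that would have ended it
  if (obs$lapse_rate > 0 && length(off_fr) > 0) {
    keep <- stats::runif(length(off_fr)) >= obs$lapse_rate
    drop_off <- off_fr[!keep]
    drop_on <- vapply(drop_off, function(f) {
      nxt <- on_fr[on_fr > f]
      if (length(nxt)) nxt[1] else NA_integer_
    }, integer(1))
    off_fr <- off_fr[keep]
    on_fr <- setdiff(on_fr, drop_on[!is.na(drop_on)])
  }
  # false alarms: one-frame spurious pairs within visible stretches
  if (obs$false_alarm_rate > 0) {
    busy <- !visible
    busy[pmax(off_fr - 1, 1)] <- TRUE
    cand <- which(visible & c(visible[-1], FALSE) & !busy)
    cand <- cand[cand < n]
    hit <- cand[stats::runif(length(cand)) < obs$false_alarm_rate]
    off_fr <- c(off_fr, hit)
    on_fr <- c(on_fr, hit + 1L)
  }
  frames <- c(off_fr, on_fr)
  if (length(frames) == 0) return(empty_response_df())
  event <- rep(c("off", "on"), c(length(off_fr), length(on_fr)))
  o <- order(frames, event == "on")
  frames <- frames[o]; event <- event[o]
  k <- length(frames)
  latency <- if (obs$latency_sd_s > 0) {
    pmax(0, stats::rnorm(k, obs$latency_mean_s, obs$latency_sd_s))
  } else {
    rep(obs$latency_mean_s, k)
  }
  data.frame(frame = frames, event = event, latency_s = latency,
             t_response_s = t[frames] + latency,
             stringsAsFactors = FALSE)
}

empty_response_df <- function() {
  data.frame(frame = integer(0), event = character(0),
             latency_s = numeric(0), t_response_s = numeric(0),
             stringsAsFactors = FALSE)
}
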