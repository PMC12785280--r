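#' Duration standardization policy
#'
#' Every recording is brought to exactly `target_s` seconds: longer
#' recordings are trimmed to their first `target_s` seconds, shorter ones are
#' extended by appending verbatim copies of the recording's initial cardiac
#' cycle (`cycle_s`, nominally 0.8 s) until the target is reached.
#'
#' @param target_s Target duration in seconds.
#' @param cycle_s Nominal cardiac-cycle duration in seconds.
#' @return A list of class `duration_policy`.
#' @export
duration_policy <- function(target_s = 3.0, cycle_s = 0.8) {
  if (!(cycle_s > 0 && cycle_s < target_s))
    stop(pcg_error("pcg_bad_policy", "need 0 < cycle_s < target_s"))
  structure(list(target_s = target_s, cycle_s = cycle_s), class = "duration_policy")
}

#' Standardize a recording to a fixed duration
#'
#' Recordings of at least `target_s` seconds keep their first `target_s`
#' seconds. Shorter recordings are extended by repeatedly appending the
#' recording's initial segment in chunks of at most one cardiac cycle
#' (`cycle_s`); the final chunk is truncated so the output is exactly
#' `round(target_s * fs)` samples. Appended material is a verbatim copy: no
#' crossfading or synthesis, and the original samples are never modified.
#' Inputs shorter than one cycle are still extended (the whole signal is
#' repeated) with a warning.
#'
#' @param rec A [pcg_recording()].
#' @param policy A [duration_policy()].
#' @return The standardized recording.
#' @export
standardize_duration <- function(rec, policy = duration_policy()) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(policy, "duration_policy"))
  x <- rec$samples
  n_target <- round(policy$target_s * rec$fs)
  if (length(x) >= n_target) {
    rec$samples <- x[seq_len(n_target)]
    return(rec)
  }
  n_cycle <- round(policy$cycle_s * rec$fs)
  if (length(x) < n_cycle)
    warning(sprintf("recording %s is shorter than one cardiac cycle (%.2f s); repeating whole signal",
                    rec$record_id, policy$cycle_s))
  chunk <- x[seq_len(min(n_cycle, length(x)))]
  out <- x
  while (length(out) < n_target) {
    need <- n_target - length(out)
    out <- c(out, chunk[seq_len(min(need, length(chunk)))])
  }
  rec$samples <- out
  rec
}
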