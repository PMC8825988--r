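#' Sonar sound groups and silent times
#'
#' Pulses emitted with short interpulse intervals form sonar sound groups;
#' the silent time is the interval between consecutive groups, measured
#' from the end of one group's last pulse to the start of the next group's
#' first pulse.
#'
#' @param pulses Data frame of one channel's focal pulses with
#'   \code{onset}, \code{offset} (s), sorted or not.
#' @param gap_threshold_ms Offset-to-onset gaps below this share a group.
#' @return List: \code{groups} (data frame \code{group_id}, \code{onset},
#'   \code{offset}, \code{n_pulses}), \code{silent_times} (numeric, s;
#'   empty when fewer than two groups), and \code{membership} (group id per
#'   pulse, in onset order).
#' @export
group_and_silent_times <- function(pulses, gap_threshold_ms = 30) {
  if (nrow(pulses) == 0L)
    return(list(groups = data.frame(group_id = integer(0), onset = numeric(0),
                                    offset = numeric(0), n_pulses = integer(0)),
                silent_times = numeric(0), membership = integer(0)))
  o <- order(pulses$onset)
  on <- pulses$onset[o]; off <- pulses$offset[o]
  gaps <- on[-1L] - off[-length(off)]
  new_group <- c(TRUE, gaps >= gap_threshold_ms / 1000)
  gid <- cumsum(new_group)
  groups <- data.frame(
    group_id = seq_len(max(gid)),
    onset = tapply(on, gid, min),
    offset = tapply(off, gid, max),
    n_pulses = as.integer(tapply(on, gid, length)))
  silent <- if (nrow(groups) >= 2L)
    groups$onset[-1L] - groups$offset[-nrow(groups)]
  else numeric(0)
  list(groups = groups, silent_times = as.numeric(silent),
       membership = gid[order(o)])
}
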