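#' Polynomial smoothing of a flight trajectory
#'
#' Fits each coordinate of a motion-capture trajectory with per-segment
#' least-squares polynomials (default order 10 over 5-s segments), the
#' standard preprocessing before differentiating positions into flight
#' directions and relative velocities. Time is rescaled to \eqn{[-1, 1]}
#' within each segment before fitting; a plain monomial basis at order 10 on
#' raw seconds would be numerically singular.
#'
#' Segmentation rule: consecutive \code{segment_len_s} windows; a leftover
#' shorter than half a window is merged into the previous segment, a longer
#' one stands alone. A 10-s flight therefore yields exactly two 5-s
#' segments.
#'
#' @param trajectory Data frame with columns \code{bat_id}, \code{frame}
#'   (0-based), \code{t_s}, \code{x_m}, \code{y_m}, \code{z_m} for a single
#'   bat (as produced by [simulate_trajectories()] or read from a
#'   trajectory TSV).
#' @param segment_len_s Segment length in seconds.
#' @param order Polynomial order per coordinate per segment.
#' @return An object of class \code{"smoothed_trajectory"}: segment
#'   boundaries, per-segment coefficient matrices, residual RMS per
#'   coordinate, frame rate, and the evaluation grid of fitted positions at
#'   the original frame times.
#' @examples
#' tr <- data.frame(bat_id = "b1", frame = 0:299, t_s = (0:299) / 30,
#'                  x_m = sin((0:299) / 30), y_m = cos((0:299) / 30),
#'                  z_m = 1.2)
#' sm <- fit_polynomials(tr)
#' sm$residual_rms
#' @export
fit_polynomials <- function(trajectory, segment_len_s = 5, order = 10) {
  req <- c("bat_id", "frame", "t_s", "x_m", "y_m", "z_m")
  if (!all(req %in% names(trajectory)))
    stop("trajectory must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (length(unique(trajectory$bat_id)) != 1L)
    stop("fit_polynomials() smooths one bat at a time", call. = FALSE)
  trajectory <- trajectory[order(trajectory$frame), ]
  t <- trajectory$t_s
  if (any(diff(trajectory$frame) != 1L))
    stop("missing frames within the flight", call. = FALSE)
  fr <- 1 / stats::median(diff(t))

  t0 <- t[1]; span <- t[length(t)] - t0
  n_seg <- max(1L, floor(span / segment_len_s))
  bounds <- t0 + segment_len_s * seq_len(n_seg - 1L)
  leftover <- span - segment_len_s * n_seg
  if (leftover >= segment_len_s / 2) bounds <- c(bounds, t0 + segment_len_s * n_seg)
  starts <- c(t0, bounds); ends <- c(bounds, t[length(t)])

  segs <- vector("list", length(starts))
  res2 <- c(x = 0, y = 0, z = 0); npt <- 0L
  for (s in seq_along(starts)) {
    # segment owns [start, end); the final segment also owns its end point
    in_seg <- t >= starts[s] & (t < ends[s] | s == length(starts))
    if (sum(in_seg) < order + 1L)
      stop(sprintf("segment %d (%.2f-%.2f s) has %d frames; need >= %d",
                   s, starts[s], ends[s], sum(in_seg), order + 1L),
           call. = FALSE)
    mid <- (starts[s] + ends[s]) / 2; half <- (ends[s] - starts[s]) / 2
    u <- (t[in_seg] - mid) / half
    X <- outer(u, 0:order, `^`)
    cf <- matrix(0, order + 1L, 3L, dimnames = list(NULL, c("x", "y", "z")))
    for (k in 1:3) {
      y <- trajectory[in_seg, c("x_m", "y_m", "z_m")[k]]
      fit <- stats::lm.fit(X, y)
      cf[, k] <- fit$coefficients
      res2[k] <- res2[k] + sum(fit$residuals^2)
    }
    npt <- npt + sum(in_seg)
    segs[[s]] <- list(start = starts[s], end = ends[s], mid = mid,
                      half = half, coef = cf)
  }
  obj <- structure(list(
    bat_id = trajectory$bat_id[1], segments = segs, order = order,
    frame_rate = fr, t0 = t0, t_end = t[length(t)],
    n_frames = nrow(trajectory),
    residual_rms = sqrt(res2 / npt)
  ), class = "smoothed_trajectory")
  obj$fitted <- predict(obj, t = t)
  obj
}

#' Evaluate a smoothed trajectory
#'
#' @param object A \code{"smoothed_trajectory"}.
#' @param t Times (s) at which to evaluate; alternatively give \code{frame}.
#' @param frame 0-based frame indices (converted via the frame rate).
#' @param ... Unused.
#' @return Data frame with \code{t_s}, \code{x}, \code{y}, \code{z}.
#' @export
predict.smoothed_trajectory <- function(object, t = NULL, frame = NULL, ...) {
  if (is.null(t)) {
    if (is.null(frame)) stop("give `t` or `frame`", call. = FALSE)
    t <- object$t0 + frame / object$frame_rate
  }
  if (any(t < object$t0 - 1e-9 | t > object$t_end + 1e-9))
    stop("evaluation time outside the fitted flight", call. = FALSE)
  starts <- vapply(object$segments, `[[`, 0, "start")
  idx <- findInterval(t, starts, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  out <- matrix(NA_real_, length(t), 3L)
  for (s in unique(idx)) {
    sg <- object$segments[[s]]
    u <- (t[idx == s] - sg$mid) / sg$half
    out[idx == s, ] <- outer(u, 0:object$order, `^`) %*% sg$coef
  }
  data.frame(t_s = t, x = out[, 1], y = out[, 2], z = out[, 3])
}

#' @exportS3Method base::print
print.smoothed_trajectory <- function(x, ...) {
  cat(sprintf(
    "Smoothed trajectory: bat %s, %d frames @ %.1f fps, %d segment(s), order %d\n",
    x$bat_id, x$n_frames, x$frame_rate, length(x$segments), x$order))
  cat(sprintf("residual RMS (m): x %.2e  y %.2e  z %.2e\n",
              x$residual_rms[1], x$residual_rms[2], x$residual_rms[3]))
  invisible(x)
}
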