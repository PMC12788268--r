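# Trajectory reconstruction from frame-wise detections: trial trimming,
# multi-ball tracking, and throw/catch event labelling.
#
# Internal conventions: vertical axis up-positive in metres, time in
# seconds, 0-based frame indices, half-open trial intervals [start, end).
# Pixel-frame tables are flipped on ingest (see `ingest_detections()`).

#' Trim a continuous detection stream into juggling trials
#'
#' A trial starts at the first frame where at least two ball candidates are
#' above the knee line and is confirmed once a candidate subsequently
#' crosses the shoulder line; it ends when fewer than two candidates remain
#' above the knee line for a hold-out duration.
#'
#' @param det a `detection_table` (see [corrupt_detections()]).
#' @param shoulder_line,knee_line threshold heights in the table's units.
#'   If `NULL` they are estimated from the hand-position height (knee =
#'   hands - 0.5, shoulder = hands + 0.25).
#' @param hold_out seconds below threshold that terminate a trial.
#' @return data frame of `TrialSegment`s: `start_t`, `end_t`, `n_frames`,
#'   `valid` (whether the shoulder line was crossed).
#' @export
trim_trials <- function(det, shoulder_line = NULL, knee_line = NULL,
                        hold_out = 0.5) {
  det <- ingest_detections(det)
  if (nrow(det) == 0) return(trial_segment_frame())
  hands <- det[det$type %in% c("hand_L", "hand_R"), ]
  if (is.null(knee_line) || is.null(shoulder_line)) {
    if (nrow(hands) == 0)
      stop("supply threshold lines or a table with hand positions", call. = FALSE)
    h <- stats::median(hands$y)
    knee_line <- knee_line %||% (h - 0.5)
    shoulder_line <- shoulder_line %||% (h + 0.25)
  }
  balls <- det[det$type == "ball", ]
  if (nrow(balls) == 0) return(trial_segment_frame())
  frames <- sort(unique(det$frame))
  tt <- tapply(det$t, det$frame, min)[as.character(frames)]
  n_above <- tabulate(match(balls$frame[balls$y > knee_line], frames),
                      nbins = length(frames))
  any_shoulder <- tabulate(match(balls$frame[balls$y > shoulder_line], frames),
                           nbins = length(frames)) > 0
  dt <- stats::median(diff(tt))
  hold_frames <- max(1L, round(hold_out / dt))

  segs <- list()
  i <- 1L; n <- length(frames)
  while (i <= n) {
    if (n_above[i] >= 2) {
      j <- i; below <- 0L; crossed <- FALSE
      while (j <= n && below < hold_frames) {
        if (n_above[j] >= 2) below <- 0L else below <- below + 1L
        if (any_shoulder[j]) crossed <- TRUE
        j <- j + 1L
      }
      end_i <- j - 1L - below
      segs[[length(segs) + 1L]] <- data.frame(
        start_t = tt[i], end_t = tt[min(end_i + 1L, n)],
        n_frames = end_i - i + 1L, valid = crossed
      )
      i <- j
    } else i <- i + 1L
  }
  if (!length(segs)) return(trial_segment_frame())
  out <- do.call(rbind, segs)
  out[out$valid, , drop = FALSE]
}

trial_segment_frame <- function() {
  data.frame(start_t = numeric(), end_t = numeric(), n_frames = integer(),
             valid = logical())
}

#' Reconstruct ball trajectories from frame-wise detections
#'
#' Greedy globally-cheapest assignment of candidates to active tracks per
#' frame under a distance gate; unmatched tracks coast on a
#' constant-velocity prediction for up to `max_gap` frames before closing;
#' unmatched candidates seed new tracks. The `n_balls` longest tracks are
#' retained.
#'
#' @param det a `detection_table`, time-ordered.
#' @param n_balls number of tracks to retain.
#' @param max_jump assignment gate: maximum candidate-to-prediction distance
#'   per frame, in the table's units.
#' @param max_gap maximum coasted frames before a track closes.
#' @return list of `ball_track`s (fields `t`, `x`, `y`, `frame`,
#'   `true_ball` where the table carries ground-truth identity). The
#'   attribute `degraded` is `TRUE` when the retained tracks cover less
#'   than 80% of frames.
#' @export
track_balls <- function(det, n_balls = 3L, max_jump = 0.25, max_gap = 5L) {
  det <- ingest_detections(det)
  balls <- det[det$type == "ball", ]
  frames <- sort(unique(det$frame))
  tt <- tapply(det$t, det$frame, min)[as.character(frames)]
  by_frame <- split(seq_len(nrow(balls)), factor(balls$frame, levels = frames))

  active <- list()   # each: x, y, vx, vy, miss, rows (indices into balls), n
  closed <- list()
  new_track <- function(row) list(x = balls$x[row], y = balls$y[row],
                                  vx = 0, vy = 0, miss = 0L, rows = row)
  for (fi in seq_along(frames)) {
    cand <- by_frame[[fi]]
    nA <- length(active); nC <- length(cand)
    matched_t <- rep(FALSE, nA); matched_c <- rep(FALSE, nC)
    if (nA > 0 && nC > 0) {
      px <- vapply(active, function(a) a$x + a$vx, 0)
      py <- vapply(active, function(a) a$y + a$vy, 0)
      D <- sqrt(outer(px, balls$x[cand], "-")^2 +
                outer(py, balls$y[cand], "-")^2)
      repeat {
        m <- which.min(D)
        if (!length(m) || D[m] > max_jump) break
        ti <- (m - 1) %% nA + 1; ci <- (m - 1) %/% nA + 1
        a <- active[[ti]]
        a$vx <- balls$x[cand[ci]] - a$x
        a$vy <- balls$y[cand[ci]] - a$y
        a$x <- balls$x[cand[ci]]; a$y <- balls$y[cand[ci]]
        a$miss <- 0L
        a$rows <- c(a$rows, cand[ci])
        active[[ti]] <- a
        matched_t[ti] <- TRUE; matched_c[ci] <- TRUE
        D[ti, ] <- Inf; D[, ci] <- Inf
      }
    }
    # coast unmatched tracks
    keep <- rep(TRUE, nA)
    for (ti in seq_len(nA)) {
      if (matched_t[ti]) next
      a <- active[[ti]]
      a$miss <- a$miss + 1L
      a$x <- a$x + a$vx; a$y <- a$y + a$vy
      if (a$miss > max_gap) {
        closed[[length(closed) + 1L]] <- a
        keep[ti] <- FALSE
      } else active[[ti]] <- a
    }
    active <- active[keep]
    # unmatched candidates seed new tracks
    for (ci in which(!matched_c))
      active[[length(active) + 1L]] <- new_track(cand[ci])
  }
  all_tracks <- c(active, closed)
  if (!length(all_tracks)) return(structure(list(), degraded = TRUE))
  lens <- vapply(all_tracks, function(a) length(a$rows), 0L)
  keep <- order(lens, decreasing = TRUE)[seq_len(min(n_balls, length(all_tracks)))]
  out <- lapply(seq_along(keep), function(i) {
    rows <- sort(all_tracks[[keep[i]]]$rows)
    structure(list(ball_id = i,
                   t = balls$t[rows], x = balls$x[rows], y = balls$y[rows],
                   frame = balls$frame[rows],
                   true_ball = if ("true_ball" %in% names(balls))
                     balls$true_ball[rows] else NULL,
                   events = empty_events()),
              class = "ball_track")
  })
  covered <- length(unique(unlist(lapply(out, `[[`, "frame"))))
  degraded <- covered < 0.8 * length(frames)
  if (degraded)
    warning("degraded tracking: retained tracks cover < 80% of frames",
            call. = FALSE)
  attr(out, "degraded") <- degraded
  out
}

#' Label throw and catch events on reconstructed tracks
#'
#' A throw is labelled at the first frame a ball leaves the hand-radius
#' neighbourhood of the holding hand with upward velocity; a catch at the
#' first frame it enters the radius of the opposite hand and remains inside
#' for at least `min_hold` frames.
#'
#' @param tracks list of `ball_track`s.
#' @param hands data frame `t`, `x_L`, `y_L`, `x_R`, `y_R` (resampled to the
#'   track time base if necessary).
#' @param hand_radius ball-hand distance threshold, m.
#' @param min_hold frames a ball must stay inside the radius to count as
#'   caught.
#' @return the tracks with the `events` field filled; tracks with no events
#'   carry attribute `no_events = TRUE`.
#' @export
label_events <- function(tracks, hands, hand_radius = 0.1, min_hold = 3L) {
  lapply(tracks, function(tr) {
    hx_L <- stats::approx(hands$t, hands$x_L, tr$t, rule = 2)$y
    hy_L <- stats::approx(hands$t, hands$y_L, tr$t, rule = 2)$y
    hx_R <- stats::approx(hands$t, hands$x_R, tr$t, rule = 2)$y
    hy_R <- stats::approx(hands$t, hands$y_R, tr$t, rule = 2)$y
    d_L <- sqrt((tr$x - hx_L)^2 + (tr$y - hy_L)^2)
    d_R <- sqrt((tr$x - hx_R)^2 + (tr$y - hy_R)^2)
    inside <- cbind(L = d_L < hand_radius, R = d_R < hand_radius)
    n <- length(tr$t)
    vy <- c(diff(tr$y), 0) / c(diff(tr$t), Inf)

    state <- if (inside[1, "L"]) "L" else if (inside[1, "R"]) "R" else "flight"
    events <- list()
    i <- 2L
    while (i <= n) {
      if (state %in% c("L", "R")) {
        if (!inside[i, state] && vy[i - 1] > 0) {
          events[[length(events) + 1L]] <-
            data.frame(kind = "throw", time = tr$t[i], hand = state,
                       stringsAsFactors = FALSE)
          state <- "flight"
        } else if (!inside[i, state]) state <- "flight"  # dropped out sideways
      } else {
        last_throw_hand <- if (length(events))
          utils::tail(events[[length(events)]]$hand, 1) else NA
        for (h in c("L", "R")) {
          if (!is.na(last_throw_hand) && h == last_throw_hand) next
          if (inside[i, h]) {
            hold_end <- min(n, i + min_hold - 1L)
            if (all(inside[i:hold_end, h]) && (hold_end - i + 1L) >= min_hold) {
              events[[length(events) + 1L]] <-
                data.frame(kind = "catch", time = tr$t[i], hand = h,
                           stringsAsFactors = FALSE)
              state <- h
            }
            break
          }
        }
      }
      i <- i + 1L
    }
    ev <- if (length(events)) do.call(rbind, events) else empty_events()
    tr$events <- ev
    if (nrow(ev) == 0) attr(tr, "no_events") <- TRUE
    tr
  })
}
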