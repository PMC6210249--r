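#' Activity classes used in the daily time budget
#'
#' Stay-point classes plus travel, in the order used by the time-budget
#' summary.
#' @export
ACTIVITY_CLASSES <- c("residence", "work", "dining", "shopping", "fitness",
                      "entertainment", "travel", "other")

#' Construct a one-day activity diary
#'
#' A diary holds the stay points (location, class, duration) and travel
#' segments (polyline, duration) of one participant-day. Durations are in
#' hours and must sum to 24 over stays plus travel: the full day is
#' partitioned between activity locations and routes.
#'
#' @param participant_id scalar identifier.
#' @param stays data.frame with columns `x`, `y` (meters), `activity_class`,
#'   `duration` (hours, > 0).
#' @param travels list of travel segments, each a list with `polyline`
#'   (m x 2 matrix, m >= 2), `duration` (hours, >= 0) and optional `mode`.
#' @param validate check the 24-hour budget and field invariants.
#' @return an object of class `activity_diary`.
#' @export
activity_diary <- function(participant_id, stays, travels = list(), validate = TRUE) {
  d <- structure(list(participant_id = participant_id,
                      stays = stays, travels = travels),
                 class = "activity_diary")
  if (validate) validate_diary(d)
  d
}

#' Validate a diary against the 24-hour budget
#'
#' Checks that stay durations are positive, coordinates finite, every travel
#' polyline has at least two vertices, and that the total of stay and travel
#' hours equals 24 within `tol`. The residual is reported on failure.
#'
#' @param diary an `activity_diary`.
#' @param tol absolute tolerance on the 24 h budget.
#' @return the diary, invisibly.
#' @export
validate_diary <- function(diary, tol = 1e-9) {
  s <- diary$stays
  if (is.null(s) || nrow(s) < 1) stop("diary has no stay points", call. = FALSE)
  if (any(!is.finite(s$x)) || any(!is.finite(s$y)))
    stop("non-finite stay coordinates", call. = FALSE)
  if (any(s$duration <= 0)) stop("stay durations must be positive", call. = FALSE)
  for (tr in diary$travels) {
    if (!is.matrix(tr$polyline) || nrow(tr$polyline) < 2)
      stop("travel polyline needs at least 2 vertices", call. = FALSE)
    if (tr$duration < 0) stop("travel duration must be nonnegative", call. = FALSE)
  }
  res <- 24 - sum(s$duration) - travel_hours(diary)
  if (abs(res) > tol)
    stop(sprintf("diary durations do not sum to 24 h (residual %.3g h)", res),
         call. = FALSE)
  invisible(diary)
}

travel_hours <- function(diary) {
  if (length(diary$travels) == 0) return(0)
  sum(vapply(diary$travels, function(tr) tr$duration, numeric(1)))
}

#' @export
print.activity_diary <- function(x, ...) {
  cat(sprintf("activity diary [%s]: %d stays (%.2f h), %d travel segments (%.2f h)\n",
              x$participant_id, nrow(x$stays), sum(x$stays$duration),
              length(x$travels), travel_hours(x)))
  invisible(x)
}

#' Read and write diary cohorts as CSV
#'
#' One row per stay or travel segment, typed by a `kind` column. Stay rows
#' carry `x`, `y`, `activity_class`, `duration`; travel rows carry
#' `duration`, `mode` and the polyline encoded as `"x1 y1;x2 y2;..."`.
#'
#' @param diaries list of `activity_diary` objects.
#' @param path CSV file path.
#' @return `read_diaries_csv` returns a list of `activity_diary` objects.
#' @export
write_diaries_csv <- function(diaries, path) {
  rows <- lapply(diaries, function(d) {
    st <- data.frame(participant_id = d$participant_id, kind = "stay",
                     x = d$stays$x, y = d$stays$y,
                     activity_class = d$stays$activity_class,
                     duration = d$stays$duration, mode = "", polyline = "",
                     stringsAsFactors = FALSE)
    if (length(d$travels) == 0) return(st)
    tv <- do.call(rbind, lapply(d$travels, function(tr) {
      data.frame(participant_id = d$participant_id, kind = "travel",
                 x = NA_real_, y = NA_real_, activity_class = "travel",
                 duration = tr$duration,
                 mode = if (is.null(tr$mode)) "" else tr$mode,
                 polyline = paste(apply(tr$polyline, 1,
                                        function(v) paste(v, collapse = " ")),
                                  collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    rbind(st, tv)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diaries_csv
#' @export
read_diaries_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$participant_id), function(g) {
    st <- g[g$kind == "stay", ]
    tvr <- g[g$kind == "travel", ]
    travels <- lapply(seq_len(nrow(tvr)), function(i) {
      pts <- strsplit(strsplit(tvr$polyline[i], ";")[[1]], " ")
      list(polyline = do.call(rbind, lapply(pts, as.numeric)),
           duration = tvr$duration[i], mode = tvr$mode[i])
    })
    activity_diary(g$participant_id[1],
                   data.frame(x = st$x, y = st$y,
                              activity_class = st$activity_class,
                              duration = st$duration,
                              stringsAsFactors = FALSE),
                   travels)
  })
}
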