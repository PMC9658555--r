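# Glycemic-dynamics features over a 15-record sliding window.
#
# With bg(0..14) the window's glucose values (oldest to newest) and
# Delta_t the registration interval:
#   d       = bg(14) - bg(0)                         end-to-end difference
#   dp(i)   = bg(i+1) - bg(i),        i = 0..13      step differences
#   dpp(i)  = bg(5i+4) - bg(5i),      i = 0..2       mini-window differences
#   v       = d / (14 * Delta_t)                     end-to-end speed
#   vp(i)   = dp(i) / Delta_t                        step speeds
#   vpp(i)  = dpp(i) / (4 * Delta_t)                 mini-window speeds
#   ap(i)   = (bg(i+2) - bg(i)) / (2 * Delta_t)^2,  i = 0..12   accelerations
# plus body weight w, and for FS2 the heart rate at the newest registration
# and its last step difference.

#' Feature names of the FS1 / FS2 sets
#'
#' @param include_hr `TRUE` for FS2 (52 features), `FALSE` for FS1 (50).
#' @return character vector in the canonical feature order.
#' @export
feature_names <- function(include_hr = FALSE) {
  nm <- c(
    "w", "d",
    paste0("dp", 0:13),
    paste0("dpp", 0:2),
    "v",
    paste0("vp", 0:13),
    paste0("vpp", 0:2),
    paste0("ap", 0:12)
  )
  if (include_hr) nm <- c(nm, "hr", "hrp")
  nm
}

#' Extract the feature vector of one 15-record window
#'
#' Computes the FS1 (50-dimensional) or FS2 (52-dimensional) feature vector
#' from a window of 15 consecutive CGM registrations (oldest first) at
#' uniform spacing. Glucose must be in mg/dL, time in minutes; the heart-rate
#' features are the value at the newest registration and its difference from
#' the previous one.
#'
#' @param bg numeric vector of exactly 15 glucose values, mg/dL.
#' @param t numeric vector of 15 registration times in minutes, strictly
#'   increasing at uniform spacing (tolerance 1e-6 min).
#' @param weight body weight in kg.
#' @param hr optional numeric vector of 15 heart-rate values, bpm; required
#'   when `include_hr`.
#' @param include_hr compute the FS2 set.
#' @return named numeric vector in [feature_names()] order.
#' @export
#' @examples
#' ramp <- 100 + 2 * (0:14)
#' f <- extract_features(ramp, t = 5 * (0:14), weight = 70)
#' f[["d"]] # 28
#' f[["v"]] # 0.4
extract_features <- function(bg, t = 5 * (0:14), weight, hr = NULL,
                             include_hr = !is.null(hr)) {
  if (length(bg) != 15) {
    stop("feature window must hold exactly 15 records", call. = FALSE)
  }
  if (length(t) != 15) {
    stop("window time vector must hold exactly 15 entries", call. = FALSE)
  }
  steps <- diff(t)
  delta_t <- steps[1]
  if (delta_t <= 0 || any(abs(steps - delta_t) > 1e-6)) {
    stop("window spacing must be uniform and positive", call. = FALSE)
  }
  if (!is.numeric(weight) || weight <= 0) {
    stop("weight must be positive", call. = FALSE)
  }
  if (include_hr && (is.null(hr) || length(hr) != 15)) {
    stop("FS2 requires 15 heart-rate values", call. = FALSE)
  }

  d <- bg[15] - bg[1]
  dp <- bg[2:15] - bg[1:14]
  dpp <- bg[c(5, 10, 15)] - bg[c(1, 6, 11)]
  v <- d / (14 * delta_t)
  vp <- dp / delta_t
  vpp <- dpp / (4 * delta_t)
  ap <- (bg[3:15] - bg[1:13]) / (2 * delta_t)^2

  out <- c(weight, d, dp, dpp, v, vp, vpp, ap)
  if (include_hr) out <- c(out, hr[15], hr[15] - hr[14])
  names(out) <- feature_names(include_hr)
  out
}

#' Build the design matrix of a labeled series or day block
#'
#' Emits one feature row per registration in chronological order. The first
#' 14 rows of every block have no complete 15-record history and are
#' zero-padded (body weight is kept); the first fully populated row is the
#' 15th registration, i.e. 75 minutes after stream initiation at the
#' 5-minute interval. Rows whose window would span a spacing irregularity
#' (a cleaned-out gap) are likewise zero-padded and flagged. The row label
#' is the exercise flag of the newest window record, so features are strictly
#' causal.
#'
#' @param records `data.frame` with columns `time`, `bg_mgdl`, `hr_bpm`,
#'   `exercise` (as in a [subject_series()] or day block), or a
#'   [subject_series()] / `day_block` object.
#' @param weight body weight in kg (taken from the object if one is given).
#' @param include_hr build FS2 rows (requires heart rate at all records).
#' @param warmup `"zero_pad"` keeps padded rows (default); `"drop"` removes
#'   them from the output.
#' @param delta_t nominal registration interval, minutes.
#' @return list with `X` (numeric matrix, [feature_names()] columns), `y`
#'   (integer labels), and `meta` (`data.frame(time, padded)`).
#' @export
build_design_matrix <- function(records, weight = NULL, include_hr = FALSE,
                                warmup = c("zero_pad", "drop"),
                                delta_t = 5) {
  warmup <- match.arg(warmup)
  if (inherits(records, "subject_series") || inherits(records, "day_block")) {
    if (is.null(weight)) weight <- records$weight
    records <- records$records
  }
  if (is.null(weight)) {
    stop("weight must be supplied", call. = FALSE)
  }
  p <- length(feature_names(include_hr))
  n <- nrow(records)
  empty <- list(
    X = matrix(numeric(0), 0, p,
      dimnames = list(NULL, feature_names(include_hr))
    ),
    y = integer(0),
    meta = data.frame(
      time = as.POSIXct(character(0), tz = "UTC"),
      padded = logical(0)
    )
  )
  if (n == 0) {
    return(empty)
  }

  bg <- records$bg_mgdl
  t_min <- series_minutes(records$time)
  hr <- records$hr_bpm
  if (include_hr && anyNA(hr)) {
    stop("FS2 requested but heart rate is absent at some records",
      call. = FALSE
    )
  }

  X <- matrix(0, n, p, dimnames = list(NULL, feature_names(include_hr)))
  X[, "w"] <- weight
  padded <- rep(TRUE, n)

  if (n >= 15) {
    # windows ending at rows 15..n whose 14 steps are all uniform
    step_bad <- abs(diff(t_min) - delta_t) > 1e-6
    cs <- c(0, cumsum(step_bad))
    ends <- 15:n
    ok_ends <- ends[cs[ends] - cs[ends - 14] == 0]
    if (length(ok_ends) > 0) {
      idx <- outer(ok_ends - 14, 0:14, "+")
      B <- matrix(bg[idx], nrow = length(ok_ends))
      X[ok_ends, "d"] <- B[, 15] - B[, 1]
      dp <- B[, 2:15, drop = FALSE] - B[, 1:14, drop = FALSE]
      X[ok_ends, paste0("dp", 0:13)] <- dp
      dpp <- B[, c(5, 10, 15), drop = FALSE] - B[, c(1, 6, 11), drop = FALSE]
      X[ok_ends, paste0("dpp", 0:2)] <- dpp
      X[ok_ends, "v"] <- (B[, 15] - B[, 1]) / (14 * delta_t)
      X[ok_ends, paste0("vp", 0:13)] <- dp / delta_t
      X[ok_ends, paste0("vpp", 0:2)] <- dpp / (4 * delta_t)
      X[ok_ends, paste0("ap", 0:12)] <-
        (B[, 3:15, drop = FALSE] - B[, 1:13, drop = FALSE]) / (2 * delta_t)^2
      if (include_hr) {
        X[ok_ends, "hr"] <- hr[ok_ends]
        X[ok_ends, "hrp"] <- hr[ok_ends] - hr[ok_ends - 1]
      }
      padded[ok_ends] <- FALSE
    }
  }

  y <- as.integer(records$exercise)
  meta <- data.frame(time = records$time, padded = padded)
  if (warmup == "drop") {
    keep <- !padded
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    meta <- meta[keep, , drop = FALSE]
  }
  list(X = X, y = y, meta = meta)
}

#' Build a pooled design matrix over day blocks
#'
#' Applies [build_design_matrix()] independently to each block (windows never
#' cross block boundaries; warm-up padding recurs at each block start) and
#' pools the rows, carrying subject and timestamp metadata.
#'
#' @param blocks list of `day_block` objects (see [extract_day_blocks()]),
#'   possibly pooled over subjects.
#' @inheritParams build_design_matrix
#' @return list with `X`, `y`, and `meta`
#'   (`data.frame(subject_id, time, padded)`).
#' @export
featurize_blocks <- function(blocks, include_hr = FALSE,
                             warmup = c("zero_pad", "drop"), delta_t = 5) {
  warmup <- match.arg(warmup)
  parts <- lapply(blocks, function(b) {
    dm <- build_design_matrix(b,
      include_hr = include_hr,
      warmup = warmup, delta_t = delta_t
    )
    dm$meta$subject_id <- b$subject_id
    dm
  })
  X <- do.call(rbind, c(
    lapply(parts, `[[`, "X"),
    list(matrix(numeric(0), 0, length(feature_names(include_hr))))
  ))
  colnames(X) <- feature_names(include_hr)
  y <- unlist(lapply(parts, `[[`, "y"))
  if (is.null(y)) y <- integer(0)
  meta_parts <- lapply(parts, `[[`, "meta")
  meta <- if (length(meta_parts) > 0) {
    do.call(rbind, meta_parts)
  } else {
    data.frame(
      time = as.POSIXct(character(0), tz = "UTC"),
      padded = logical(0), subject_id = character(0)
    )
  }
  rownames(meta) <- NULL
  list(X = X, y = as.integer(y), meta = meta)
}
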