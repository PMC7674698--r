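# Renal excretion biokinetics: minute-by-minute source distribution for a
# Tc-99m DTPA dynamic kidney test under graded split kidney function.
#
# Model: the administered activity is taken up by the two kidneys at t = 0
# as an equal bilateral split (uptake does not depend on function level;
# see the methods vignette for why the reported gonad doses require this),
# and each kidney excretes into the bladder content on a time scale set by
# its function level f; excretion completes at 20/f min (f = 1 reproduces
# the nominal 20-min transit). Three washout laws are provided:
#   plateau (default): the kidney holds its share through the parenchymal
#     transit and releases it at 20/f min;
#   linear: constant-rate drainage, f/20 of the initial content per minute;
#   exponential: rate constant f/20 per minute (never completes).
# A kidney with f = 0 retains its share indefinitely under every law.
# Radioactive decay is NOT applied here; it enters through the decay weight
# of the dose integral.

#' Define a kidney-test scenario
#'
#' @param function_left,function_right Kidney function levels in `[0, 1]`
#'   (1 = normal; the study grades abnormality as 0.75, 0.5, 0.25, 0).
#' @param B0 Administered activity in mCi (default 1, so doses read as
#'   mGy/mCi).
#' @param sex `"male"` or `"female"`.
#' @param T_min Integration horizon in minutes. Default follows the
#'   reference comparison convention: 100 min when both kidneys are normal,
#'   1000 min when either side is degraded.
#' @param frame_min Frame length in minutes (default 1).
#' @param uptake `"equal"`: both kidneys take up half of the activity
#'   regardless of function (default); `"proportional"`: uptake split
#'   proportional to function levels.
#' @param washout Drainage law: `"plateau"` (default; the kidney holds its
#'   share through the 20/f-min parenchymal transit, then releases it),
#'   `"linear"` (constant-rate drainage completing at 20/f min) or
#'   `"exponential"` (rate constant f/20 per minute).
#' @return A `scenario` object.
#' @export
#' @examples
#' scenario(1, 1)            # normal: T = 100 min
#' scenario(0, 1)$T_min      # degraded side present: 1000 min
scenario <- function(function_left = 1, function_right = 1, B0 = 1,
                     sex = c("male", "female"), T_min = NULL, frame_min = 1,
                     uptake = c("equal", "proportional"),
                     washout = c("plateau", "linear", "exponential")) {
  sex <- match.arg(sex)
  uptake <- match.arg(uptake)
  washout <- match.arg(washout)
  if (function_left < 0 || function_left > 1 ||
      function_right < 0 || function_right > 1)
    stop("function levels must lie in [0, 1]")
  if (B0 <= 0) stop("B0 must be positive")
  if (is.null(T_min))
    T_min <- if (function_left == 1 && function_right == 1) 100 else 1000
  if (T_min <= 0) stop("T_min must be positive")
  structure(list(function_left = function_left,
                 function_right = function_right, B0 = B0, sex = sex,
                 T_min = T_min, frame_min = frame_min, uptake = uptake,
                 washout = washout), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> f_left=%.2f f_right=%.2f B0=%g mCi sex=%s T=%g min (%s/%s)\n",
    x$function_left, x$function_right, x$B0, x$sex, x$T_min, x$uptake,
    x$washout))
  invisible(x)
}

.uptake_weights <- function(scn) {
  f <- c(scn$function_left, scn$function_right)
  if (scn$uptake == "equal" || sum(f) == 0) c(0.5, 0.5) else f / sum(f)
}

#' Build the per-minute time-activity sequence of a scenario
#'
#' Emits the fraction of administered activity in each source compartment
#' (`kidney_L`, `kidney_R`, `bladder_content`) for frames m = 0..59, the
#' 60-minute dynamic test window. Frame m carries the distribution at t = m
#' minutes. Fractions sum to 1 in every frame (no decay here), the bladder
#' fraction is non-decreasing, and a kidney with function 0 stays constant
#' at its uptake weight.
#'
#' @param scn A `scenario`.
#' @param n_frames Number of 1-min frames (default 60).
#' @return A `time_activity`: numeric matrix (frames x compartments) with
#'   attribute `frame_min`.
#' @export
#' @examples
#' ta <- build_time_activity(scenario(1, 1))          # plateau transit
#' ta[11, "kidney_L"]   # frame m = 10: still 0.5
#' ta_lin <- build_time_activity(scenario(1, 1, washout = "linear"))
#' ta_lin[11, "kidney_L"]   # 0.25 (half of its initial 0.5)
build_time_activity <- function(scn, n_frames = 60) {
  stopifnot(inherits(scn, "scenario"))
  u <- .uptake_weights(scn)
  f <- c(scn$function_left, scn$function_right)
  t <- (seq_len(n_frames) - 1) * scn$frame_min
  kid <- matrix(0, n_frames, 2)
  for (k in 1:2) {
    kid[, k] <- if (f[k] == 0) {
      u[k]
    } else {
      switch(scn$washout,
        plateau = u[k] * (t < 20 / f[k]),
        linear = u[k] * pmax(0, 1 - f[k] * t / 20),
        exponential = u[k] * exp(-f[k] * t / 20))
    }
  }
  ta <- cbind(kidney_L = kid[, 1], kidney_R = kid[, 2],
              bladder_content = 1 - kid[, 1] - kid[, 2])
  structure(ta, frame_min = scn$frame_min, class = "time_activity")
}

#' Extend a time-activity sequence to an integration horizon
#'
#' Frames beyond the simulated dynamic window repeat the final
#' distribution: bladder-held and retained-kidney activity stay where they
#' are (no voiding, no further transfer) out to `T_min`.
#'
#' @param ta A `time_activity`.
#' @param T_min Horizon in minutes; must be >= the current duration.
#' @return The extended `time_activity` (returned unchanged if `T_min`
#'   equals the current duration).
#' @export
extend_to_horizon <- function(ta, T_min) {
  fm <- attr(ta, "frame_min")
  dur <- nrow(ta) * fm
  if (T_min < dur) stop("T_min (", T_min, ") is shorter than the sequence (",
                        dur, " min); cannot truncate")
  extra <- ceiling(T_min / fm) - nrow(ta)
  if (extra == 0) return(ta)
  tail_frame <- ta[nrow(ta), , drop = FALSE]
  out <- rbind(unclass(ta), tail_frame[rep(1, extra), , drop = FALSE])
  rownames(out) <- NULL
  structure(out, frame_min = fm, class = "time_activity")
}

#' Chronic kidney disease stage from the glomerular filtration rate
#'
#' NKF-K/DOQI staging with half-open bins: stage 1 for GFR >= 90, 2 for
#' 60-89, 3 for 30-59, 4 for 15-29, 5 below 15 (kidney failure/dialysis),
#' in mL/min/1.73 m^2.
#'
#' @param gfr GFR value(s), must be non-negative.
#' @return Integer stage(s) in 1..5.
#' @export
#' @examples
#' gfr_stage(c(95, 45, 14.9))  # 1 3 5
gfr_stage <- function(gfr) {
  if (any(gfr < 0)) stop("GFR cannot be negative")
  5L - findInterval(gfr, c(15, 30, 60, 90))
}

#' Export a time-activity sequence as CSV
#'
#' Long format with columns `minute`, `compartment`, `fraction`.
#'
#' @param ta A `time_activity`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_time_activity <- function(ta, path) {
  fm <- attr(ta, "frame_min")
  long <- data.frame(
    minute = rep((seq_len(nrow(ta)) - 1) * fm, ncol(ta)),
    compartment = rep(colnames(ta), each = nrow(ta)),
    fraction = as.vector(unclass(ta)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
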