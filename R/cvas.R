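#' Critical Vehicle Approach Speed (CVAS)
#'
#' For a species following a spatial margin of safety (constant FID across
#' vehicle speeds), CVAS is the vehicle speed above which the animal cannot
#' clear the collision path in time even with perfect detection and
#' monitoring: the threshold FID divided by the escape time, expressed in
#' km/h.
#'
#' @param fid_threshold Threshold FID maintained irrespective of vehicle
#'   speed, m. Vectorized.
#' @param escape_time Time needed to clear the vehicle path once escape is
#'   initiated, s.
#' @return CVAS in km/h (unrounded; reports round to the nearest integer).
#' @examples
#' cvas(28, 0.80) # 126 km/h, brown-headed cowbird
#' cvas(70, 2.1)  # 120 km/h
#' @export
cvas <- function(fid_threshold, escape_time) {
  if (any(fid_threshold < 0)) abort("`fid_threshold` must be non-negative (m).")
  if (any(escape_time <= 0)) abort("`escape_time` must be positive (s).")
  (fid_threshold / escape_time) * KMH_PER_MS
}

#' Human-readable CVAS report
#'
#' Computes CVAS and prints the collision-risk interpretation: vehicles
#' traveling at or above the CVAS are collision-prone for the species, even
#' under ideal detection conditions.
#'
#' @inheritParams cvas
#' @param quiet Suppress printing and just return the tibble.
#' @return Invisibly (or visibly when `quiet = TRUE`), a tibble with columns
#'   `fid_threshold_m`, `escape_time_s`, `cvas_ms`, `cvas_kmh` (rounded to
#'   the nearest km/h).
#' @examples
#' cvas_report(28, 0.80)
#' @export
cvas_report <- function(fid_threshold, escape_time, quiet = FALSE) {
  v_ms <- fid_threshold / escape_time
  out <- tibble(
    fid_threshold_m = fid_threshold,
    escape_time_s = escape_time,
    cvas_ms = v_ms,
    cvas_kmh = round(v_ms * KMH_PER_MS)
  )
  if (!quiet) {
    for (i in seq_len(nrow(out))) {
      cat(sprintf(
        "CVAS: %d km/h (%.2f m/s) for FID threshold %.2f m and escape time %.2f s\n",
        out$cvas_kmh[i], out$cvas_ms[i], out$fid_threshold_m[i],
        out$escape_time_s[i]))
      cat("Vehicles at or above this speed are collision-prone for this species.\n")
    }
  }
  if (quiet) out else invisible(out)
}
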