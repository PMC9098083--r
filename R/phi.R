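#' Phi index of the alert distance vs. FID relationship
#'
#' The phi index measures how closely observed FIDs track alert distances
#' along the 1:1 line through the origin in AD-FID space. It is implemented
#' as the per-observation standardized proximity to that line,
#' \deqn{\Phi = 1 - \mathrm{mean}\left(\frac{AD_i - FID_i}{AD_i}\right)
#'       = \mathrm{mean}(FID_i / AD_i),}
#' so that \eqn{\Phi = 1} when every animal escapes at the moment of alert
#' (FID = AD), \eqn{\Phi = 0} when no animal escapes at all (FID = 0), and
#' the null expectation under FID uniform on `(0, AD)` is 0.5. Values above
#' 0.5 are consistent with the flush early and avoid the rush (FEAR)
#' hypothesis.
#'
#' @param alert_distances Alert distances, m. All positive.
#' @param fids Flight initiation distances, m, with `0 <= fid <= ad`.
#' @return Phi in `[0, 1]`.
#' @examples
#' phi_index(c(10, 20), c(5, 10)) # 0.5
#' @export
phi_index <- function(alert_distances, fids) {
  check_ad_fid(alert_distances, fids)
  mean(fids / alert_distances)
}

check_ad_fid <- function(alert_distances, fids) {
  if (length(alert_distances) != length(fids) || length(fids) == 0L) {
    abort("`alert_distances` and `fids` must be non-empty and of equal length.")
  }
  if (any(alert_distances <= 0)) abort("All alert distances must be positive.")
  if (any(fids < 0) || any(fids > alert_distances)) {
    abort("FIDs must satisfy 0 <= FID <= AD.")
  }
  invisible(TRUE)
}

#' Monte-Carlo significance of an observed phi index
#'
#' Simulates the null distribution of the phi index by drawing, for each
#' observed alert distance, a FID uniform on `(0, AD)`, and returns the
#' proportion of simulated phi values at least as large as the observed
#' one. The FEAR hypothesis is supported when the observed phi exceeds 0.5
#' *and* this p-value is below 0.05.
#'
#' @param alert_distances Observed alert distances, m.
#' @param observed_phi Observed phi index in `[0, 1]`.
#' @param n_sim Number of simulated phi values.
#' @param seed Optional integer seed for reproducibility.
#' @return Monte-Carlo p-value in `[0, 1]`.
#' @examples
#' phi_significance(rep(100, 30), 0.9, n_sim = 200, seed = 1)
#' @export
phi_significance <- function(alert_distances, observed_phi, n_sim = 1000,
                             seed = NULL) {
  if (any(alert_distances <= 0)) abort("All alert distances must be positive.")
  if (observed_phi < 0 || observed_phi > 1) {
    abort("`observed_phi` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- length(alert_distances)
  sims <- matrix(runif(n_sim * m), nrow = n_sim)
  phi_sim <- rowMeans(sims) # FID/AD ratios are uniform on (0, 1)
  mean(phi_sim >= observed_phi)
}

#' FEAR-hypothesis predicted FID
#'
#' Fits a through-origin least-squares line `FID = b * AD` (the FEAR
#' hypothesis fixes the intercept at zero: no alert, no escape) and
#' predicts the FID at the 5th percentile of the observed alert distances
#' -- the distance below which only 5% of individuals had yet to become
#' alert.
#'
#' @inheritParams phi_index
#' @return Predicted FID in m.
#' @examples
#' ad <- c(30, 40, 50, 60)
#' fear_predicted_fid(ad, 0.5 * ad)
#' @export
fear_predicted_fid <- function(alert_distances, fids) {
  check_ad_fid(alert_distances, fids)
  if (length(alert_distances) < 3L) abort("At least 3 observations are required.")
  if (sd(alert_distances) == 0 && alert_distances[1] == 0) {
    abort("Degenerate alert distances.")
  }
  b <- sum(alert_distances * fids) / sum(alert_distances^2)
  b * unname(quantile(alert_distances, 0.05, type = 7))
}
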