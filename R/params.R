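#' Tracing parameters
#'
#' Bundles every tunable constant of the tracing pipeline with its default.
#' Defaults follow the settings reported to work best on fundus imagery:
#' affinity sharpness `k = 5`, critical angle `theta_c = 80` degrees,
#' critical spur length `C_critical = 10` pixels, spur angle threshold
#' `beta_critical = 70` degrees, propagation mixing `alpha = 0.9` and
#' convergence tolerance `epsilon = 1e-5`.
#'
#' @param k positive real; sharpness of the orientation affinity functions.
#' @param theta_c critical angle in degrees (0 < theta_c < 90) at which the
#'   first affinity function plateaus.
#' @param theta_star degrees; third breakpoint of the first affinity
#'   function. Default `NULL` resolves to
#'   `acos(-sin(theta_c)^k / k)`, the unique value making the function
#'   continuous; override only to explore alternative readings.
#' @param C_critical pixels; maximal length of a connector segment treated as
#'   a skeletonization artifact.
#' @param beta_critical degrees; maximal flanking angle of a removable spur.
#' @param orientation_window number of skeleton points averaged per segment
#'   end when estimating its orientation.
#' @param secant_window chain offset (pixels) of the per-point secant used in
#'   image-free orientation mode.
#' @param hessian_sigma pixels; Gaussian scale of the Hessian used for
#'   orientation when a grayscale image is available.
#' @param alpha label-propagation mixing coefficient in (0, 1).
#' @param epsilon Frobenius-norm convergence tolerance of propagation.
#' @param max_iters iteration cap for propagation.
#'
#' @return a named list of class `trace_params`.
#' @export
trace_params <- function(k = 5, theta_c = 80, theta_star = NULL,
                         C_critical = 10, beta_critical = 70,
                         orientation_window = 10, secant_window = 5,
                         hessian_sigma = 2,
                         alpha = 0.9, epsilon = 1e-5, max_iters = 10000) {
  stopifnot(k > 0, theta_c > 0, theta_c < 90,
            orientation_window >= 2, alpha > 0, alpha < 1, epsilon > 0)
  if (is.null(theta_star))
    theta_star <- rad2deg(acos(-sin(deg2rad(theta_c))^k / k))
  structure(list(k = k, theta_c = theta_c, theta_star = theta_star,
                 C_critical = C_critical, beta_critical = beta_critical,
                 orientation_window = orientation_window,
                 secant_window = secant_window,
                 hessian_sigma = hessian_sigma,
                 alpha = alpha, epsilon = epsilon, max_iters = max_iters),
            class = "trace_params")
}
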