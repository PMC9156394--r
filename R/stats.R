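#' Maximum graft stagnation by anastomotic angle (reference table)
#'
#' Reference values of maximum cross-sectional stagnation percentage in the
#' graft vessel at the five anastomotic angles of the study design, used by
#' [fit_table3()] as the packaged input of the stagnation-versus-angle
#' regression.
#'
#' @format data.frame with columns `angle_deg` and `max_stagnation_pct`.
#' @export
diep_stagnation <- data.frame(
  angle_deg = c(30, 45, 60, 75, 90),
  max_stagnation_pct = c(26.82, 32.51, 35.63, 39.62, 41.58))

#' Ordinary least-squares fit of stagnation versus angle
#'
#' Fits `stagnation = slope * angle + intercept` by OLS (via [stats::lm()])
#' and reports the coefficient of determination `r_squared = 1 - SSres /
#' SStot`. When the response has zero variance, `r_squared` is reported as
#' 0 by convention, with a warning.
#'
#' @param angles numeric vector of angles (degrees).
#' @param stagnation numeric vector of stagnation percentages, same length.
#' @return an object of class `linear_fit` with fields `slope` (% per
#'   degree), `intercept` (%), `r_squared`, `n`, and the `fitted` values.
#' @examples
#' ols_fit(c(30, 45, 60, 75, 90), c(26.82, 32.51, 35.63, 39.62, 41.58))
#' @export
ols_fit <- function(angles, stagnation) {
  if (length(angles) != length(stagnation))
    stop("angles and stagnation must have the same length")
  if (length(angles) < 2) stop("at least two points are required")
  if (length(unique(angles)) < 2)
    stop("no variance in angles: at least two distinct angles required")
  fit <- stats::lm(stagnation ~ angles)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((stagnation - mean(stagnation))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance response: r_squared reported as 0 by convention")
    0
  } else 1 - ss_res / ss_tot
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, n = length(angles),
                 angles = angles, stagnation = stagnation,
                 fitted = unname(stats::fitted(fit))),
            class = "linear_fit")
}

#' Predict stagnation from a linear fit
#' @param object a `linear_fit`.
#' @param angle angle(s) in degrees.
#' @param ... unused.
#' @return predicted stagnation percentage(s).
#' @export
predict.linear_fit <- function(object, angle, ...) {
  object$slope * angle + object$intercept
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit (n = %d): y = %.3gx + %.3g, R^2 = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Fit the packaged stagnation-by-angle table
#'
#' OLS fit of [diep_stagnation] (maximum graft stagnation percentage versus
#' anastomotic angle). This is the reference regression path, independent
#' of any flow solution.
#'
#' @return a `linear_fit`.
#' @examples
#' fit_table3()
#' @export
fit_table3 <- function() {
  ols_fit(diep_stagnation$angle_deg, diep_stagnation$max_stagnation_pct)
}
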