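#' One-site equilibrium binding fit
#'
#' Fits the one-site model \code{R_eq(C) = Rmax * C / (Kd + C)} to an
#' equilibrium concentration-response series by nonlinear least
#' squares, as used for surface plasmon resonance equilibrium analysis.
#' Initialization: Kd at the concentration of half-maximal response,
#' Rmax at 1.1x the maximal response.  A series with no measurable
#' curvature over the tested range (the apparent Kd runs far beyond the
#' highest concentration) is reported as a lower-bound failure rather
#' than a number.
#'
#' @param concentrations analyte concentrations (same unit throughout,
#'   e.g. nM; >= 3 distinct nonzero values).
#' @param responses equilibrium responses (response units).
#' @param kd_ceiling_factor declare failure when the fitted Kd exceeds
#'   this multiple of the highest concentration.
#' @return object of class \code{"one_site_fit"}: list with
#'   \code{Kd}, \code{Rmax}, \code{rss}, \code{se} (named standard
#'   errors), \code{converged}, \code{failure} (NULL or a reason
#'   string), \code{data}.
#' @export
fit_one_site <- function(concentrations, responses,
                         kd_ceiling_factor = 25) {
  conc <- as.numeric(concentrations)
  resp <- as.numeric(responses)
  if (length(conc) != length(resp))
    stopf("concentrations and responses must have equal length")
  ok <- is.finite(conc) & is.finite(resp) & conc >= 0
  conc <- conc[ok]; resp <- resp[ok]
  if (length(unique(conc[conc > 0])) < 3L)
    stopf("need at least 3 distinct nonzero concentrations")
  rmax0 <- 1.1 * max(resp)
  half <- max(resp) / 2
  kd0 <- tryCatch(stats::approx(resp, conc, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
  dat <- data.frame(conc = conc, resp = resp)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(resp ~ Rmax * conc / (Kd + conc), data = dat,
                 start = list(Rmax = rmax0, Kd = kd0),
                 algorithm = "port",
                 lower = c(Rmax = 1e-12, Kd = 1e-12),
                 control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  failure <- NULL
  if (is.null(fit)) {
    failure <- "fit did not converge"
  } else {
    est <- stats::coef(fit)
    if (est[["Kd"]] > kd_ceiling_factor * max(conc))
      failure <- sprintf(
        "no curvature over the tested range: Kd > %.3g (lower bound only)",
        kd_ceiling_factor * max(conc))
  }
  if (!is.null(failure)) {
    return(structure(list(Kd = NA_real_, Rmax = NA_real_, rss = NA_real_,
                          se = c(Kd = NA_real_, Rmax = NA_real_),
                          converged = FALSE, failure = failure,
                          data = dat, fit = fit),
                     class = "one_site_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(Rmax = NA_real_, Kd = NA_real_))
  structure(list(Kd = unname(est[["Kd"]]), Rmax = unname(est[["Rmax"]]),
                 rss = sum(stats::residuals(fit)^2),
                 se = c(Kd = unname(se[["Kd"]]), Rmax = unname(se[["Rmax"]])),
                 converged = TRUE, failure = NULL,
                 data = dat, fit = fit),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  if (!x$converged) {
    cat("One-site binding fit FAILED:", x$failure, "\n")
  } else {
    cat(sprintf("One-site binding fit: Kd = %.4g (se %.3g), Rmax = %.4g (se %.3g), RSS = %.3g\n",
                x$Kd, x$se[["Kd"]], x$Rmax, x$se[["Rmax"]], x$rss))
  }
  invisible(x)
}

#' @export
coef.one_site_fit <- function(object, ...) {
  c(Kd = object$Kd, Rmax = object$Rmax)
}

#' @export
predict.one_site_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else {
    if (is.list(newdata)) newdata$conc %||% newdata[[1]] else as.numeric(newdata)
  }
  object$Rmax * conc / (object$Kd + conc)
}

#' @export
residuals.one_site_fit <- function(object, ...) {
  object$data$resp - predict(object)
}

#' @export
plot.one_site_fit <- function(x, ...) {
  graphics::plot(x$data$conc, x$data$resp, xlab = "concentration",
                 ylab = "equilibrium response", ...)
  if (x$converged) {
    cs <- seq(0, max(x$data$conc), length.out = 200)
    graphics::lines(cs, x$Rmax * cs / (x$Kd + cs))
  }
  invisible(x)
}

#' Read a binding series CSV and fit it
#'
#' Expects two columns: concentration and equilibrium response.
#'
#' @param path CSV path.
#' @return a \code{\link{fit_one_site}} result.
#' @export
fit_binding_csv <- function(path) {
  df <- utils::read.csv(path)
  fit_one_site(df[[1]], df[[2]])
}
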