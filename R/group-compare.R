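# One-way ANOVA with Dunnett many-to-one contrasts, computed either from
# raw measurements or from printed group summaries (mean, spread, n).
# The Dunnett adjustment is computed in-house from the multivariate-t
# distribution of the contrast statistics: the balanced/unbalanced
# correlation structure rho_ij = lambda_i * lambda_j with
# lambda_i = sqrt(n_i / (n_i + n_0)) factorizes, so the family-wise
# probability reduces to a double integral over the common control
# factor and the scale chi variable, evaluated by adaptive quadrature
# (with a seeded Monte Carlo fallback).

# P(max_i |T_i| <= q) for the two-sided Dunnett statistic with df nu and
# loading vector lambda.
dunnett_cdf <- function(q, nu, lambda, method = c("quadrature", "mc"),
                        mc_draws = 1e6, mc_seed = 20260921) {
  method <- match.arg(method)
  if (q <= 0) return(0)
  k <- length(lambda)
  if (method == "mc") {
    return(with_seed(mc_seed, {
      z0 <- stats::rnorm(mc_draws)
      s <- sqrt(stats::rchisq(mc_draws, nu) / nu)
      inside <- rep(TRUE, mc_draws)
      for (i in seq_len(k)) {
        ti <- (lambda[i] * z0 +
                 sqrt(1 - lambda[i]^2) * stats::rnorm(mc_draws)) / s
        inside <- inside & abs(ti) <= q
      }
      mean(inside)
    }))
  }
  inner <- function(s1) {
    # s1 is scalar: P(all |X_i| <= q*s1) for X ~ N(0, R)
    f <- function(z) {
      out <- stats::dnorm(z)
      for (i in seq_len(k)) {
        sdi <- sqrt(1 - lambda[i]^2)
        out <- out * (stats::pnorm((q * s1 - lambda[i] * z) / sdi) -
                        stats::pnorm((-q * s1 - lambda[i] * z) / sdi))
      }
      out
    }
    stats::integrate(f, -8.5, 8.5, rel.tol = 1e-9)$value
  }
  # outer integral over s = sqrt(chi^2_nu / nu); log-density for stability
  lds <- function(s) {
    log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) +
      (nu - 1) * log(s) - nu * s^2 / 2
  }
  outer_f <- function(sv) vapply(sv, function(s) exp(lds(s)) * inner(s), 0)
  lo <- max(1e-8, 1 - 10 / sqrt(nu))
  hi <- 1 + 10 / sqrt(nu)
  if (nu < 10) { lo <- 1e-8; hi <- 12 }
  stats::integrate(outer_f, lo, hi, rel.tol = 1e-8)$value
}

# Two-sided Dunnett-adjusted p for observed |t| = tq.
dunnett_p_adjust <- function(tq, nu, lambda, method = "quadrature",
                             mc_seed = 20260921) {
  p <- 1 - dunnett_cdf(abs(tq), nu, lambda, method = method,
                       mc_seed = mc_seed)
  min(max(p, 0), 1)
}

as_group_summary <- function(g, se_is_sd = FALSE) {
  # Accept period_set, raw numeric vector, or list(mean, sd|sem, n).
  if (inherits(g, "period_set")) g <- g$periods_nm
  if (is.numeric(g) && length(g) > 1L) {
    return(list(mean = mean(g), sd = stats::sd(g), n = length(g)))
  }
  if (is.list(g)) {
    n <- g$n %||% stopf("group summary needs n")
    m <- g$mean %||% g$mean_nm %||% stopf("group summary needs mean")
    if (!is.null(g$sd) || !is.null(g$sd_nm)) {
      s <- g$sd %||% g$sd_nm
    } else if (!is.null(g$sem) || !is.null(g$sem_nm)) {
      s <- (g$sem %||% g$sem_nm) * sqrt(n)
    } else if (!is.null(g$pm)) {
      # a printed "mean +/- x" value: read per `se_is_sd`
      s <- if (se_is_sd) g$pm else g$pm * sqrt(n)
    } else stopf("group summary needs sd, sem or pm")
    return(list(mean = m, sd = s, n = n))
  }
  stopf("cannot interpret group input")
}

#' Compare treatment groups to a control (ANOVA + Dunnett)
#'
#' Pooled-variance one-way analysis of variance followed by two-sided
#' Dunnett many-to-one comparisons of each treatment against the
#' control.  Groups may be given as raw measurement vectors,
#' \code{\link{period_set}} objects, or printed summaries
#' \code{list(mean =, sd = | sem = | pm =, n =)}.  A printed
#' \code{pm} ("plus-minus") value is read as a standard error by
#' default; set \code{pm_is_sd = TRUE} to read it as a standard
#' deviation.
#'
#' @param control control group (vector, period set or summary list).
#' @param treatments named list of treatment groups in the same forms.
#' @param pm_is_sd how to read a bare \code{pm} spread in summaries.
#' @param method \code{"quadrature"} (default) or \code{"mc"} for the
#'   Dunnett family-wise probability; the Monte Carlo fallback uses at
#'   least 1e6 seeded draws.
#' @param mc_seed seed for the Monte Carlo fallback.
#' @return object of class \code{"group_comparison"}: list with
#'   \code{F}, \code{df_between}, \code{df_within}, \code{p_anova},
#'   and a \code{comparisons} data frame (condition, mean_diff,
#'   t, p_unadjusted, adjusted_p).
#' @export
compare_to_control <- function(control, treatments, pm_is_sd = FALSE,
                               method = c("quadrature", "mc"),
                               mc_seed = 20260921) {
  method <- match.arg(method)
  if (!is.list(treatments) || inherits(treatments, "period_set"))
    treatments <- list(treatments)
  if (length(treatments) < 1L) stopf("need at least one treatment group")
  ctrl <- as_group_summary(control, se_is_sd = pm_is_sd)
  trts <- lapply(treatments, as_group_summary, se_is_sd = pm_is_sd)
  labels <- names(treatments) %||% paste0("treatment", seq_along(trts))
  if (is.null(names(treatments)) || any(!nzchar(labels)))
    labels <- ifelse(nzchar(names(treatments) %||% ""), names(treatments),
                     paste0("treatment", seq_along(trts)))
  all_groups <- c(list(ctrl), trts)
  ns <- vapply(all_groups, `[[`, 0, "n")
  ms <- vapply(all_groups, `[[`, 0, "mean")
  sds <- vapply(all_groups, `[[`, 0, "sd")
  if (any(ns < 2)) stopf("every group needs n >= 2")
  k <- length(all_groups)
  N <- sum(ns)
  grand <- sum(ns * ms) / N
  ss_between <- sum(ns * (ms - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df_b <- k - 1L
  df_w <- N - k
  if (ss_within <= 0) stopf("zero within-group variance everywhere")
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  Fstat <- ms_b / ms_w
  p_anova <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  lambda <- sqrt(ns[-1] / (ns[-1] + ns[1]))
  comp <- lapply(seq_along(trts), function(i) {
    se <- sqrt(ms_w * (1 / ns[i + 1] + 1 / ns[1]))
    t <- (ms[i + 1] - ms[1]) / se
    data.frame(condition = labels[i],
               mean_diff = ms[i + 1] - ms[1],
               t = t,
               p_unadjusted = 2 * stats::pt(abs(t), df_w, lower.tail = FALSE),
               adjusted_p = dunnett_p_adjust(t, df_w, lambda,
                                             method = method,
                                             mc_seed = mc_seed))
  })
  structure(list(F = Fstat, df_between = df_b, df_within = df_w,
                 p_anova = p_anova,
                 comparisons = do.call(rbind, comp),
                 method = paste0("one-way ANOVA + Dunnett (", method, ")")),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s\nF(%d, %d) = %.3f, p = %.3g\n", x$method,
              x$df_between, x$df_within, x$F, x$p_anova))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Pooled-variance unpaired Student t-test
#'
#' Thin wrapper over \code{stats::t.test(var.equal = TRUE)} returning
#' the statistic, degrees of freedom and p-value.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param two_sided logical; two-sided by default.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
unpaired_t_test <- function(a, b, two_sided = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("each sample needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = TRUE,
                      alternative = if (two_sided) "two.sided" else "less")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
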