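#' Parametric survival families
#'
#' Registry of the six parametric time-to-event families used for
#' extrapolation: exponential, Weibull, Gompertz, lognormal, log-logistic
#' and generalized gamma. The generalized gamma uses the
#' location--scale--shape (mu, sigma, Q) parameterization, in which the
#' Weibull (Q = 1/sigma... Q = 1) and lognormal (Q -> 0) arise as special
#' cases; distribution functions are delegated to \pkg{stats} and
#' \pkg{flexsurv}.
#'
#' @format A named list; each element gives the parameter names, their
#'   lower domain bounds (on the natural scale) and the number of free
#'   parameters `k`.
#' @keywords internal
survival_families <- list(
  exponential = list(pars = c("rate"), lower = c(rate = 0), k = 1L),
  weibull = list(pars = c("shape", "scale"), lower = c(shape = 0, scale = 0), k = 2L),
  gompertz = list(pars = c("shape", "rate"), lower = c(shape = -Inf, rate = 0), k = 2L),
  lognormal = list(pars = c("meanlog", "sdlog"), lower = c(meanlog = -Inf, sdlog = 0), k = 2L),
  loglogistic = list(pars = c("shape", "scale"), lower = c(shape = 0, scale = 0), k = 2L),
  generalized_gamma = list(pars = c("mu", "sigma", "Q"),
                           lower = c(mu = -Inf, sigma = 0, Q = -Inf), k = 3L)
)

#' Construct a parametric survival model from explicit parameters
#'
#' Builds a `survmodel` object that the cohort engines and outcome
#' functions can evaluate, without requiring a fit to data. Fitted models
#' returned by [fit_parametric()] share this class.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`, `"generalized_gamma"`.
#' @param params Named numeric vector of parameters on the natural scale
#'   (e.g. `c(rate = 0.002)`; time unit is days throughout).
#' @return An object of class `survmodel`.
#' @examples
#' m <- survmodel("exponential", c(rate = 0.01))
#' survival_at(m, 100)   # exp(-1)
#' @export
survmodel <- function(family, params) {
  family <- match.arg(family, names(survival_families))
  spec <- survival_families[[family]]
  params <- unlist(params)
  if (!all(spec$pars %in% names(params))) {
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(spec$pars, collapse = ", ")), call. = FALSE)
  }
  params <- params[spec$pars]
  # exponential rate 0 is admitted (degenerate: no events ever)
  if (family != "exponential" && any(params <= spec$lower & is.finite(spec$lower))) {
    stop(sprintf("parameters out of domain for family '%s'", family), call. = FALSE)
  }
  if (any(!is.finite(params))) {
    stop(sprintf("non-finite parameters for family '%s'", family), call. = FALSE)
  }
  structure(list(family = family, params = params, loglik = NA_real_,
                 n = NA_integer_, n_event = NA_integer_, k = spec$k,
                 AIC = NA_real_, AICc = NA_real_, BIC = NA_real_,
                 converged = TRUE),
            class = "survmodel")
}

#' @export
print.survmodel <- function(x, ...) {
  cat(sprintf("<survmodel: %s>\n", x$family))
  print(signif(x$params, 5))
  if (!is.na(x$loglik)) {
    cat(sprintf("logLik %.3f  n=%d events=%d  AIC %.2f  AICc %.2f  BIC %.2f  %s\n",
                x$loglik, x$n, x$n_event, x$AIC, x$AICc, x$BIC,
                if (isTRUE(x$converged)) "converged" else "NOT CONVERGED"))
  }
  invisible(x)
}

#' Evaluate the survival function of a parametric model
#'
#' @param model A `survmodel`.
#' @param t Vector of non-negative times (days).
#' @return `S(t)`, a probability in `[0, 1]`; `S(0) = 1`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "survmodel"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- model$params
  s <- switch(model$family,
    exponential = stats::pexp(t, rate = p[["rate"]], lower.tail = FALSE),
    weibull = stats::pweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                              lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                                   lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                              lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]],
                                    lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                            Q = p[["Q"]], lower.tail = FALSE)
  )
  pmin(pmax(s, 0), 1)
}

#' Evaluate the hazard function of a parametric model
#'
#' @inheritParams survival_at
#' @return `h(t) = f(t) / S(t)` where `S(t) > 0`.
#' @export
hazard_at <- function(model, t) {
  stopifnot(inherits(model, "survmodel"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- model$params
  switch(model$family,
    exponential = flexsurv::hexp(t, rate = p[["rate"]]),
    weibull = flexsurv::hweibull(t, shape = p[["shape"]], scale = p[["scale"]]),
    gompertz = flexsurv::hgompertz(t, shape = p[["shape"]], rate = p[["rate"]]),
    lognormal = flexsurv::hlnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    loglogistic = flexsurv::hllogis(t, shape = p[["shape"]], scale = p[["scale"]]),
    generalized_gamma = flexsurv::hgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                            Q = p[["Q"]])
  )
}

# Random draws from a family spec list(family=, params=); rate-0 exponential
# yields Inf (the event never happens). Used by the cohort generator.
rsurv <- function(n, spec) {
  p <- spec$params
  switch(spec$family,
    exponential = if (p[["rate"]] <= 0) rep(Inf, n) else stats::rexp(n, rate = p[["rate"]]),
    weibull = stats::rweibull(n, shape = p[["shape"]], scale = p[["scale"]]),
    gompertz = flexsurv::rgompertz(n, shape = p[["shape"]], rate = p[["rate"]]),
    lognormal = stats::rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    loglogistic = flexsurv::rllogis(n, shape = p[["shape"]], scale = p[["scale"]]),
    generalized_gamma = flexsurv::rgengamma(n, mu = p[["mu"]], sigma = p[["sigma"]],
                                            Q = p[["Q"]]),
    stop(sprintf("unknown family '%s'", spec$family), call. = FALSE)
  )
}

validate_hazard_spec <- function(spec, edge) {
  if (!is.list(spec) || is.null(spec$family) || is.null(spec$params)) {
    stop(sprintf("invalid hazard spec for edge '%s'", edge), call. = FALSE)
  }
  if (!spec$family %in% names(survival_families)) {
    stop(sprintf("unknown family '%s' for edge '%s'", spec$family, edge), call. = FALSE)
  }
  fam <- survival_families[[spec$family]]
  pars <- unlist(spec$params)
  if (!all(fam$pars %in% names(pars))) {
    stop(sprintf("edge '%s' (%s) needs parameters: %s", edge, spec$family,
                 paste(fam$pars, collapse = ", ")), call. = FALSE)
  }
  pars <- pars[fam$pars]
  if (any(!is.finite(pars))) {
    stop(sprintf("non-finite hazard parameters on edge '%s'", edge), call. = FALSE)
  }
  lw <- fam$lower
  # exponential rate may be 0 (edge switched off); other strictly-positive
  # parameters must exceed their bound
  strict <- is.finite(lw) & !(spec$family == "exponential" & names(lw) == "rate")
  if (any(pars[strict] <= lw[strict]) || any(pars[!strict & is.finite(lw)] < lw[!strict & is.finite(lw)])) {
    stop(sprintf("hazard parameters out of domain on edge '%s'", edge), call. = FALSE)
  }
  list(family = spec$family, params = pars)
}
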