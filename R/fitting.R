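#' Kaplan--Meier estimate for an endpoint dataset
#'
#' Product-limit estimator with Greenwood standard errors, via
#' [survival::survfit()]. Deaths are processed before censorings at tied
#' times, as usual for the product-limit estimator. The median is the
#' smallest time at which the estimate drops to 0.5 or below, `NA` if
#' never reached.
#'
#' @param data Data frame with `time` (days, > 0) and `event` (logical).
#' @return A `km_estimate` list: `time`, `surv`, `n_risk`, `n_event`,
#'   `greenwood_se`, `median`.
#' @export
km_estimate <- function(data) {
  stopifnot(nrow(data) >= 1, all(data$time > 0))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                          conf.type = "log-log")
  med <- if (any(sf$surv <= 0.5)) min(sf$time[sf$surv <= 0.5]) else NA_real_
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event,
                 greenwood_se = sf$surv * sf$std.err,
                 median = med, n = nrow(data)),
            class = "km_estimate")
}

# flexsurv distribution codes for the six families
.flexsurv_dist <- c(exponential = "exp", weibull = "weibull",
                    gompertz = "gompertz", lognormal = "lnorm",
                    loglogistic = "llogis", generalized_gamma = "gengamma")

#' Fit a parametric survival family by maximum likelihood
#'
#' Right-censored maximum likelihood via [flexsurv::flexsurvreg()]. For
#' the generalized gamma and Gompertz families additional starting
#' points are tried when the default fit fails or does not converge; a
#' still-unconverged fit is returned flagged (and excluded from model
#' selection) rather than raising an error. Information criteria use the
#' number of subjects `n`: `AIC = 2k - 2l`, `AICc = AIC +
#' 2k(k+1)/(n-k-1)`, `BIC = k log(n) - 2l`.
#'
#' @param data Data frame with `time` (> 0) and `event` (logical).
#' @param family Family name, see [survival_families].
#' @return A `fitted_survmodel` (also a `survmodel`).
#' @export
fit_parametric <- function(data, family) {
  family <- match.arg(family, names(survival_families))
  n <- nrow(data)
  n_event <- sum(data$event)
  if (n_event < 1) stop("all observations censored; cannot fit", call. = FALSE)
  dist <- .flexsurv_dist[[family]]
  try_fit <- function(inits = NULL) {
    args <- list(survival::Surv(time, event) ~ 1, data = data, dist = dist,
                 control = list(reltol = 1e-12, maxit = 500))
    if (!is.null(inits)) args$inits <- inits
    tryCatch(
      suppressWarnings(do.call(flexsurv::flexsurvreg, args)),
      error = function(e) NULL)
  }
  fit <- try_fit()
  ok <- function(f) !is.null(f) && is.finite(f$loglik) &&
    all(is.finite(f$res[, "est"])) && isTRUE(f$opt$convergence == 0)
  if (!ok(fit) && family %in% c("generalized_gamma", "gompertz")) {
    # restart from moment-style inits on the log-time scale
    lt <- log(data$time[data$event])
    alt <- if (family == "generalized_gamma") {
      list(c(mean(lt), stats::sd(lt), 1), c(mean(lt), stats::sd(lt), 0.5),
           c(mean(lt), stats::sd(lt), -0.5))
    } else {
      r0 <- n_event / sum(data$time)
      list(c(1e-6, r0), c(0.001, r0), c(-0.001, r0))
    }
    for (ini in alt) {
      f2 <- try_fit(ini)
      if (ok(f2)) { fit <- f2; break }
      if (is.null(fit) && !is.null(f2)) fit <- f2
    }
  }
  if (is.null(fit)) {
    m <- structure(list(family = family, params = NULL, loglik = NA_real_,
                        n = n, n_event = n_event,
                        k = survival_families[[family]]$k,
                        AIC = NA_real_, AICc = NA_real_, BIC = NA_real_,
                        converged = FALSE),
                   class = c("fitted_survmodel", "survmodel"))
    return(m)
  }
  params <- fit$res[, "est"]
  names(params) <- rownames(fit$res)
  # harmonize names with the family registry
  names(params) <- sub("^rate$", "rate", names(params))
  k <- survival_families[[family]]$k
  ll <- fit$loglik
  aic <- 2 * k - 2 * ll
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  m <- survmodel(family, params)
  m$loglik <- ll
  m$n <- n
  m$n_event <- n_event
  m$AIC <- aic
  m$AICc <- aicc
  m$BIC <- k * log(n) - 2 * ll
  m$converged <- ok(fit)
  class(m) <- c("fitted_survmodel", "survmodel")
  m
}

#' Fit all (or a subset of) parametric families to one endpoint
#'
#' @param data Endpoint data frame (`time`, `event`).
#' @param families Families to fit (default all six).
#' @return Named list of `fitted_survmodel`s.
#' @export
fit_families <- function(data, families = names(survival_families)) {
  stats::setNames(lapply(families, function(f) fit_parametric(data, f)),
                  families)
}

#' Select the best-fitting parametric model
#'
#' Default winner is the converged model with the lowest AIC (AICc and
#' BIC are reported alongside); ties are broken by fewer parameters,
#' then by the fixed family order of [survival_families]. An explicit
#' `override` names a family to force, standing in for visual
#' inspection of the fitted curves.
#'
#' @param models Named list of `fitted_survmodel`s.
#' @param criterion `"aic"`, `"aicc"` or `"bic"`.
#' @param override Optional family name to select regardless of the
#'   criterion.
#' @return List with `best` (the chosen model) and `ranking` (data frame
#'   of family, k, loglik, AIC, AICc, BIC, converged, ordered by the
#'   criterion).
#' @export
select_best <- function(models, criterion = c("aic", "aicc", "bic"),
                        override = NULL) {
  criterion <- match.arg(criterion)
  tab <- data.frame(
    family = vapply(models, `[[`, "", "family"),
    k = vapply(models, `[[`, 0L, "k"),
    loglik = vapply(models, `[[`, 0, "loglik"),
    AIC = vapply(models, `[[`, 0, "AIC"),
    AICc = vapply(models, `[[`, 0, "AICc"),
    BIC = vapply(models, `[[`, 0, "BIC"),
    converged = vapply(models, function(m) isTRUE(m$converged), FALSE),
    row.names = NULL
  )
  conv <- tab$converged
  if (!any(conv)) stop("no converged models to select from", call. = FALSE)
  crit_col <- c(aic = "AIC", aicc = "AICc", bic = "BIC")[[criterion]]
  fam_order <- match(tab$family, names(survival_families))
  ord <- order(!conv, ifelse(conv, tab[[crit_col]], Inf), tab$k, fam_order)
  ranking <- tab[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  best_fam <- if (!is.null(override)) {
    override <- match.arg(override, names(survival_families))
    if (!isTRUE(tab$converged[tab$family == override])) {
      stop(sprintf("override family '%s' did not converge", override), call. = FALSE)
    }
    override
  } else ranking$family[1]
  list(best = models[[best_fam]], ranking = ranking)
}

#' Proportional-hazards diagnostics between two arms
#'
#' Fits a two-arm Cox proportional-hazards model, computes the scaled
#' Schoenfeld-residual trend test per covariate and the global
#' chi-square test ([survival::cox.zph()]), and returns the
#' log-cumulative-hazard (log(-log S)) Kaplan--Meier curves for visual
#' assessment.
#'
#' @param data_a,data_b Endpoint data frames for the two arms (`time`,
#'   `event`); both must contain at least one event.
#' @return A `ph_diagnostics` list: `hazard_ratio`, `schoenfeld` (data
#'   frame of per-term chi-square and p), `global_p`, `verdict`
#'   (`TRUE` when the global test does not reject at 5%), `loglog`
#'   (per-arm `time`, `loglog` curves).
#' @export
test_proportional_hazards <- function(data_a, data_b) {
  if (sum(data_a$event) < 1 || sum(data_b$event) < 1) {
    stop("both arms need at least one event", call. = FALSE)
  }
  d <- rbind(data.frame(time = data_a$time, event = data_a$event, arm = "A"),
             data.frame(time = data_b$time, event = data_b$event, arm = "B"))
  cx <- survival::coxph(survival::Surv(time, event) ~ arm, data = d)
  zp <- survival::cox.zph(cx)
  tab <- as.data.frame(zp$table)
  loglog <- lapply(split(d, d$arm), function(dd) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = dd)
    keep <- sf$surv > 0 & sf$surv < 1
    list(time = sf$time[keep], loglog = log(-log(sf$surv[keep])))
  })
  gp <- tab["GLOBAL", "p"]
  structure(list(
    hazard_ratio = unname(exp(stats::coef(cx))),
    schoenfeld = tab,
    global_p = gp,
    verdict = gp > 0.05,
    loglog = loglog
  ), class = "ph_diagnostics")
}
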