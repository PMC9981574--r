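# Toxicity endpoints: immobility counts per concentration, a
# two-parameter log-logistic EC50 estimator with binomial likelihood,
# and lab-vs-device concordance.

#' Immobility counts per concentration
#'
#' Applies the immobility endpoint ([mobileCount()]) to each chamber's
#' trajectories and returns a dose-response table: the number of immobile
#' animals is the chamber population minus the mobile count.
#'
#' @param trajsByConc named list of trajectory data.frames, one per
#'   concentration; names are the concentrations.
#' @param nTotal exposed population per chamber (scalar or vector
#'   parallel to `trajsByConc`).
#' @param fps,windowSeconds,epsilon immobility parameters as in
#'   [stationaryFilter()].
#' @return data.frame with columns `concentration, n_total, n_immobile`.
#' @export
immobilityTable <- function(trajsByConc, nTotal, fps = 15,
                            windowSeconds = 20, epsilon = 0.5) {
  conc <- as.numeric(names(trajsByConc))
  if (anyNA(conc)) stop("trajsByConc must be named by concentration")
  nTotal <- rep_len(nTotal, length(trajsByConc))
  mobile <- vapply(trajsByConc, mobileCount, integer(1), fps = fps,
                   windowSeconds = windowSeconds, epsilon = epsilon)
  if (any(mobile > nTotal))
    stop("mobile count exceeds the chamber population; ",
         "tracking may have split identities")
  data.frame(concentration = conc, n_total = nTotal,
             n_immobile = nTotal - as.integer(mobile), row.names = NULL)
}

ec50NLL <- function(par, conc, n, k, link) {
  logE <- par[1]; slope <- exp(par[2])
  eta <- slope * (log(conc) - logE)
  p <- if (link == "logit") stats::plogis(eta) else stats::pnorm(eta)
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -sum(stats::dbinom(k, n, p, log = TRUE))
}

#' Fit a two-parameter log-logistic dose-response curve
#'
#' Maximum-likelihood fit of
#' \eqn{P(\mathrm{immobile} \mid c) = 1/(1 + (EC_{50}/c)^{slope})}
#' with a binomial likelihood (equivalently, a logistic model in
#' log-concentration). The optimiser is deterministic: Nelder-Mead on
#' `(log EC50, log slope)` starting from the geometric mean of the two
#' concentrations bracketing the 50% response and slope 1. Zero
#' concentrations (controls) are excluded from the likelihood.
#'
#' @param records data.frame with columns
#'   `concentration, n_total, n_immobile`.
#' @param link `"logit"` (log-logistic, default) or `"probit"`.
#' @param ci `"none"` or `"bootstrap"` (seeded nonparametric binomial
#'   resampling per concentration).
#' @param nboot,seed,level bootstrap settings.
#' @param extrapolate allow fitting when the observed response fractions
#'   never cross 50% (default FALSE: such data give an error instead of a
#'   silent extrapolation).
#' @return An [Ec50Fit-class].
#' @examples
#' rec <- data.frame(concentration = c(0.5, 1, 2, 4, 8),
#'                   n_total = 20, n_immobile = c(1, 4, 10, 16, 19))
#' fitEC50(rec)
#' @export
fitEC50 <- function(records, link = c("logit", "probit"),
                    ci = c("none", "bootstrap"), nboot = 200L,
                    seed = 1L, level = 0.95, extrapolate = FALSE) {
  link <- match.arg(link); ci <- match.arg(ci)
  need <- c("concentration", "n_total", "n_immobile")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  r <- records[records$concentration > 0, , drop = FALSE]
  if (length(unique(r$concentration)) < 3)
    stop("need at least 3 distinct positive concentrations")
  if (any(r$n_immobile < 0 | r$n_immobile > r$n_total))
    stop("n_immobile must lie in [0, n_total]")
  frac <- r$n_immobile / r$n_total
  if (all(frac <= 0) || all(frac >= 1))
    stop("responses are all 0 or all 1; no dose-response to fit")
  cu <- sort(unique(r$concentration))
  fr <- vapply(cu, function(cc) {
    sum(r$n_immobile[r$concentration == cc]) /
      sum(r$n_total[r$concentration == cc])
  }, numeric(1))
  crosses <- any(fr <= 0.5) && any(fr >= 0.5)
  if (!crosses && !extrapolate)
    stop("observed responses never cross 50%; refusing to extrapolate ",
         "(set extrapolate = TRUE to override)")
  # starting EC50: geometric mean of the concentrations bracketing 50%
  below <- which(fr <= 0.5); above <- which(fr >= 0.5)
  e0 <- if (crosses) {
    sqrt(cu[max(below)] * cu[min(above)])
  } else {
    exp(mean(log(cu)))
  }
  fit1 <- function(n_immobile) {
    opt <- stats::optim(c(log(e0), log(1)), ec50NLL, conc = r$concentration,
                        n = r$n_total, k = n_immobile, link = link,
                        control = list(maxit = 2000, reltol = 1e-12))
    c(ec50 = exp(opt$par[1]), slope = exp(opt$par[2]),
      nll = opt$value, conv = opt$convergence)
  }
  est <- fit1(r$n_immobile)
  ciVec <- NA_real_
  if (ci == "bootstrap") {
    set.seed(deriveSeed(seed, 202L))
    phat <- pmin(1, pmax(0, r$n_immobile / r$n_total))
    boots <- replicate(nboot, {
      kStar <- stats::rbinom(nrow(r), r$n_total, phat)
      tryCatch(fit1(kStar)["ec50"], error = function(e) NA_real_)
    })
    a <- (1 - level) / 2
    ciVec <- as.numeric(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE))
  }
  new("Ec50Fit", ec50 = unname(est["ec50"]), slope = unname(est["slope"]),
      logLik = -unname(est["nll"]), converged = est["conv"] == 0,
      ci = ciVec, records = records, link = link)
}

#' Predicted immobile fraction at given concentrations
#'
#' @param fit an [Ec50Fit-class].
#' @param conc numeric concentrations.
#' @return Predicted probabilities of immobility.
#' @export
predictImmobility <- function(fit, conc) {
  eta <- fit@slope * (log(conc) - log(fit@ec50))
  if (fit@link == "logit") stats::plogis(eta) else stats::pnorm(eta)
}

#' Lab-vs-device concordance
#'
#' Squared Pearson correlation between paired laboratory and device
#' measurements, plus the least-squares line relating them.
#'
#' @param lab,device paired numeric vectors, `n >= 2`.
#' @return List with `r_squared`, `slope`, `intercept`, `n`.
#' @examples
#' concordance(c(1, 2, 3), c(3, 5, 7))
#' @export
concordance <- function(lab, device) {
  if (length(lab) != length(device) || length(lab) < 2)
    stop("need paired vectors of length >= 2")
  if (stats::sd(lab) == 0 || stats::sd(device) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r_squared = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(lab)))
  }
  fit <- stats::lm(device ~ lab)
  list(r_squared = unname(stats::cor(lab, device)^2),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(lab))
}
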