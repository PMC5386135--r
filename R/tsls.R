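#' Two-stage least squares with a single instrument
#'
#' Just-identified TSLS of `outcome` on `exposure` using `instrument`, with
#' covariates entering both stages symmetrically. The standard error is the
#' homoskedastic IV formula with second-stage residuals formed from the
#' observed (not fitted) exposure; a heteroskedasticity-robust sandwich
#' option is available but off by default. The partial F statistic for the
#' excluded instrument, conditional on the covariates, is reported as the
#' weak-instrument diagnostic.
#'
#' @param exposure,outcome,instrument numeric vectors of equal length.
#' @param covariates optional numeric matrix / data.frame of covariates
#'   included in both stages.
#' @param robust use a heteroskedasticity-robust (HC0) variance instead of
#'   the homoskedastic formula.
#' @param method_label label carried into the returned estimate.
#' @return an `iv_estimate`: `method_label`, `beta` (SD outcome per SD
#'   exposure), `se`, `ci_low`, `ci_high` (beta -/+ 1.96 se), `n_used`,
#'   `first_stage_F`.
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(200); x <- z + rnorm(200); y <- 0.5 * x + rnorm(200)
#' tsls(x, y, z)
tsls <- function(exposure, outcome, instrument, covariates = NULL,
                 robust = FALSE, method_label = "tsls") {
  n <- length(exposure)
  if (length(outcome) != n || length(instrument) != n)
    stop("exposure, outcome and instrument must have equal length",
         call. = FALSE)
  W <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(W) && nrow(W) != n)
    stop("covariates must have one row per observation", call. = FALSE)

  keep <- stats::complete.cases(exposure, outcome, instrument,
                                if (is.null(W)) rep(0, n) else W)
  exposure <- exposure[keep]; outcome <- outcome[keep]
  instrument <- instrument[keep]
  if (!is.null(W)) W <- W[keep, , drop = FALSE]
  n <- sum(keep)
  p_cov <- if (is.null(W)) 0L else ncol(W)
  if (n < p_cov + 3L)
    stop("insufficient data: need at least covariates + 3 observations",
         call. = FALSE)
  if (stats::var(instrument) == 0)
    stop("instrument is constant", call. = FALSE)

  WW <- cbind(`(Intercept)` = rep(1, n), W)
  Z <- cbind(WW, instrument = instrument)       # first-stage design
  if (qr(Z)$rank < ncol(Z))
    stop("singular design: instrument or covariates are collinear",
         call. = FALSE)

  fs <- stats::lm.fit(Z, exposure)
  xhat <- fs$fitted.values
  rss1 <- sum(fs$residuals^2)
  rss0 <- sum(stats::lm.fit(WW, exposure)$residuals^2)
  first_stage_F <- (rss0 - rss1) / (rss1 / (n - ncol(Z)))

  D <- cbind(exposure = xhat, WW)               # second-stage design
  if (qr(D)$rank < ncol(D))
    stop("singular design in the second stage", call. = FALSE)
  fit2 <- stats::lm.fit(D, outcome)
  theta <- fit2$coefficients
  # structural residuals: observed exposure, not first-stage fitted values
  e <- outcome - cbind(exposure = exposure, WW) %*% theta
  DtD_inv <- chol2inv(chol(crossprod(D)))
  V <- if (robust) {
    meat <- crossprod(D * as.vector(e))
    DtD_inv %*% meat %*% DtD_inv
  } else {
    sigma2 <- sum(e^2) / (n - ncol(D))
    sigma2 * DtD_inv
  }
  beta <- unname(theta[1])
  se <- sqrt(V[1, 1])
  iv_estimate(method_label, beta, se, n, first_stage_F)
}

iv_estimate <- function(method_label, beta, se, n_used, first_stage_F = NA) {
  structure(list(
    method_label = method_label, beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    n_used = as.integer(n_used), first_stage_F = first_stage_F
  ), class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.3f (SE %.3f, 95%% CI %.3f to %.3f), n = %d",
              x$method_label, x$beta, x$se, x$ci_low, x$ci_high, x$n_used))
  if (is.finite(x$first_stage_F))
    cat(sprintf(", first-stage F = %.1f", x$first_stage_F))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.iv_estimate <- function(x, ...) {
  data.frame(method = x$method_label, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, n_used = x$n_used,
             first_stage_F = x$first_stage_F)
}

#' Estimate the causal intrauterine effect under all adjustment strategies
#'
#' Runs the four estimation strategies compared in the simulation design,
#' plus the transmitted-score comparator:
#' (1) `unadjusted` - instrument the maternal exposure by the maternal allele
#' score `G_m`, no covariates; (2) `offspring_adjusted` - as (1) with the
#' offspring score `G_o` in both stages; (3) `offspring_paternal_adjusted` -
#' additionally the paternal score `G_p`; (4) `nontransmitted` - instrument
#' by the maternal non-transmitted haplotype score `G_nt`, no covariates;
#' (5) `transmitted` - instrument by the transmitted score `G_t`, the
#' contrast that isolates what transmission contributes.
#'
#' @param cohort a `trio_cohort` with all scores populated.
#' @param strategies subset of the five labels to run.
#' @param robust passed to [tsls()].
#' @return named list of `iv_estimate` objects (class `iv_estimate_list`).
#' @export
estimate_all_strategies <- function(cohort,
                                    strategies = c("unadjusted",
                                                   "offspring_adjusted",
                                                   "offspring_paternal_adjusted",
                                                   "nontransmitted",
                                                   "transmitted"),
                                    robust = FALSE) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  run <- list(
    unadjusted = function() tsls(cohort$X_m, cohort$Y_o, cohort$G_m,
                                 robust = robust, method_label = "unadjusted"),
    offspring_adjusted = function()
      tsls(cohort$X_m, cohort$Y_o, cohort$G_m,
           covariates = cbind(G_o = cohort$G_o), robust = robust,
           method_label = "offspring_adjusted"),
    offspring_paternal_adjusted = function()
      tsls(cohort$X_m, cohort$Y_o, cohort$G_m,
           covariates = cbind(G_o = cohort$G_o, G_p = cohort$G_p),
           robust = robust, method_label = "offspring_paternal_adjusted"),
    nontransmitted = function() tsls(cohort$X_m, cohort$Y_o, cohort$G_nt,
                                     robust = robust,
                                     method_label = "nontransmitted"),
    transmitted = function() tsls(cohort$X_m, cohort$Y_o, cohort$G_t,
                                  robust = robust,
                                  method_label = "transmitted")
  )
  out <- lapply(run[strategies], function(f) f())
  structure(out, class = "iv_estimate_list")
}

#' @export
as.data.frame.iv_estimate_list <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' @export
print.iv_estimate_list <- function(x, ...) {
  for (e in unclass(x)) print(e)
  invisible(x)
}

#' Probability limit of the unadjusted estimate
#'
#' Closed form for the large-sample value of the unadjusted strategy under
#' the generative model with no assortment or pleiotropy:
#' `gamma + 0.5 * sqrt(v_o / q_x)`. The 0.5 is the parent-offspring score
#' correlation: the maternal instrument reaches the outcome through the
#' transmitted half of the offspring genotype, violating the exclusion
#' restriction in proportion to the offspring direct path.
#'
#' @param gamma true causal effect (SD/SD).
#' @param q_x variance of exposure explained by the maternal score (> 0).
#' @param v_o variance of outcome explained by the offspring direct path.
#' @return expected unadjusted estimate, SD outcome per SD exposure.
#' @seealso [expected_offspring_adjusted_estimate()]
#' @export
#' @examples
#' expected_unadjusted_estimate(0, 0.02, 0.05)    # 0.79
#' expected_unadjusted_estimate(0.10, 0.02, 0.05) # 0.89
expected_unadjusted_estimate <- function(gamma, q_x, v_o) {
  if (q_x <= 0)
    stop("undefined instrument: q_x must be positive", call. = FALSE)
  gamma + 0.5 * sqrt(v_o / q_x)
}

#' Probability limit of the offspring-adjusted estimate
#'
#' Conditioning both stages on the offspring score opens the collider path:
#' given `G_o`, the maternal and paternal scores are negatively correlated
#' (partial correlation -1/3 when spousal correlation is zero), so any
#' paternal direct path leaks into the estimate with a negative sign. The
#' closed form is `gamma - sqrt(v_p / q_x) / 3`.
#'
#' @inheritParams expected_unadjusted_estimate
#' @param v_p variance of outcome explained by the paternal direct path.
#' @return expected offspring-adjusted estimate, SD outcome per SD exposure.
#' @export
expected_offspring_adjusted_estimate <- function(gamma, q_x, v_p) {
  if (q_x <= 0)
    stop("undefined instrument: q_x must be positive", call. = FALSE)
  gamma - sqrt(v_p / q_x) / 3
}

#' Instrument-confounder balance diagnostics
#'
#' Regresses each observed potential confounder on the maternal score `G_m`,
#' with or without adjustment for the offspring score - the recommended check
#' that the instrument is unrelated to confounders, run both ways because
#' offspring-genotype adjustment can itself induce association through the
#' collider.
#'
#' @param cohort a `trio_cohort`.
#' @param confounders data.frame or matrix of observed confounder columns.
#' @param adjust_offspring also condition on `G_o`.
#' @return data.frame: one row per confounder with the `G_m` coefficient,
#'   standard error and p-value.
#' @export
confounder_balance_check <- function(cohort, confounders,
                                     adjust_offspring = FALSE) {
  confounders <- as.data.frame(confounders)
  if (ncol(confounders) < 1L)
    stop("at least one confounder column is required", call. = FALSE)
  X <- cbind(1, G_m = cohort$G_m,
             if (adjust_offspring) cbind(G_o = cohort$G_o))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
  out <- lapply(names(confounders), function(nm) {
    fit <- stats::lm.fit(X, confounders[[nm]])
    sigma2 <- sum(fit$residuals^2) / (nrow(X) - ncol(X))
    V <- sigma2 * chol2inv(chol(crossprod(X)))
    b <- fit$coefficients[2]
    se <- sqrt(V[2, 2])
    data.frame(confounder = nm, coef_G_m = unname(b), se = se,
               p_value = 2 * stats::pnorm(-abs(b / se)),
               adjusted_for_offspring = adjust_offspring)
  })
  do.call(rbind, out)
}
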