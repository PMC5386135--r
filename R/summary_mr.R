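#' Per-variant exposure and outcome association summaries
#'
#' Computes, for each panel variant, the per-allele association of the
#' maternal dosage with the maternal exposure and with the offspring outcome,
#' the inputs to the summary-statistic sensitivity estimators ([ivw()],
#' [mr_egger()], [weighted_median()]). With `adjust_offspring = TRUE`
#' (recommended) the outcome model conditions on the offspring's dosage at
#' the same variant, blocking the transmitted path that otherwise violates
#' the InSIDE assumption when maternal exposure and offspring outcome are the
#' same trait. Effects are harmonized last: each variant is oriented so its
#' exposure association is non-negative, flipping the outcome association
#' jointly.
#'
#' Exposure associations may instead be supplied externally (e.g. from an
#' independent GWAS); internal weights are the default but carry the usual
#' one-sample weak-instrument caveat, so a message is logged.
#'
#' @param cohort a `trio_cohort` retaining per-variant dosage matrices.
#' @param adjust_offspring condition the outcome regression on the offspring
#'   dosage of the same variant.
#' @param external_beta_x optional data.frame with columns `beta_x`, `se_x`
#'   (one row per variant) replacing the internal exposure regressions.
#' @return data.frame of class `variant_summary`: `variant`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `oriented` (all `TRUE` after harmonization).
#'   Monomorphic variants are excluded with a warning.
#' @export
per_variant_summaries <- function(cohort, adjust_offspring = TRUE,
                                  external_beta_x = NULL) {
  M <- cohort$maternal_genotype
  O <- cohort$offspring_genotype
  m <- ncol(M)
  if (is.null(external_beta_x))
    message("using internally estimated exposure weights; ",
            "one-sample internal weights can amplify weak-instrument bias")

  simple_slope <- function(g, y) {
    X <- cbind(1, g)
    fit <- stats::lm.fit(X, y)
    sigma2 <- sum(fit$residuals^2) / (length(y) - 2L)
    Vinv <- chol2inv(chol(crossprod(X)))
    c(fit$coefficients[2], sqrt(sigma2 * Vinv[2, 2]))
  }
  adj_slope <- function(g, g2, y) {
    X <- cbind(1, g, g2)
    fit <- stats::lm.fit(X, y)
    sigma2 <- sum(fit$residuals^2) / (length(y) - 3L)
    Vinv <- chol2inv(chol(crossprod(X)))
    c(fit$coefficients[2], sqrt(sigma2 * Vinv[2, 2]))
  }

  rows <- vector("list", m)
  dropped <- integer(0)
  for (j in seq_len(m)) {
    g <- M[, j]
    if (stats::var(g) == 0) { dropped <- c(dropped, j); next }
    bx <- if (is.null(external_beta_x)) simple_slope(g, cohort$X_m)
          else c(external_beta_x$beta_x[j], external_beta_x$se_x[j])
    by <- if (adjust_offspring) adj_slope(g, O[, j], cohort$Y_o)
          else simple_slope(g, cohort$Y_o)
    rows[[j]] <- data.frame(variant = j, beta_x = bx[1], se_x = bx[2],
                            beta_y = by[1], se_y = by[2])
  }
  if (length(dropped))
    warning("excluding monomorphic variant(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no polymorphic variants available", call. = FALSE)
  orient_summaries(out)
}

#' Harmonize variant summaries to a positive exposure effect
#'
#' @param summaries data.frame with `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @return the same rows with `beta_x >= 0` (outcome effects flipped
#'   jointly) and `oriented = TRUE`; class `variant_summary`.
#' @export
orient_summaries <- function(summaries) {
  flip <- summaries$beta_x < 0
  summaries$beta_x[flip] <- -summaries$beta_x[flip]
  summaries$beta_y[flip] <- -summaries$beta_y[flip]
  summaries$oriented <- TRUE
  class(summaries) <- c("variant_summary", "data.frame")
  summaries
}

check_summaries <- function(summaries, min_n, caller) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) < min_n)
    stop(sprintf("%s requires at least %d variant summaries", caller, min_n),
         call. = FALSE)
  if (any(summaries$se_x <= 0, na.rm = TRUE) || any(summaries$se_y <= 0))
    stop("standard errors must be positive", call. = FALSE)
  if (is.null(summaries$oriented) || !all(summaries$oriented))
    summaries <- orient_summaries(summaries)
  summaries
}

# mean per-variant F as the weak-instrument flag shared by the summary
# estimators; one-sample performance of IVW/Egger degrades quickly below ~10
warn_weak <- function(summaries) {
  Fbar <- mean((summaries$beta_x / summaries$se_x)^2, na.rm = TRUE)
  if (is.finite(Fbar) && Fbar < 10)
    warning(sprintf(paste0(
      "mean per-variant F = %.1f (< 10): IVW and MR-Egger estimates are ",
      "vulnerable to weak-instrument bias in a one-sample analysis"), Fbar),
      call. = FALSE)
  invisible(Fbar)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of the per-variant outcome associations on the
#' exposure associations, constrained through the origin (exclusion
#' restriction assumed), with weights `1/se_y^2`; equivalently the weighted
#' mean of per-variant ratio estimates. The standard error carries a
#' multiplicative overdispersion factor bounded below by 1.
#'
#' @param summaries a `variant_summary` data.frame (>= 2 rows).
#' @return an `iv_estimate` with `method_label = "ivw"`.
#' @export
ivw <- function(summaries) {
  summaries <- check_summaries(summaries, 2L, "ivw")
  warn_weak(summaries)
  w <- 1 / summaries$se_y^2
  bx <- summaries$beta_x; by <- summaries$beta_y
  denom <- sum(w * bx^2)
  if (denom == 0) stop("degenerate regression: all beta_x are zero",
                       call. = FALSE)
  beta <- sum(w * bx * by) / denom
  k <- nrow(summaries)
  disp <- sum(w * (by - beta * bx)^2) / (k - 1L)
  se <- sqrt(max(disp, 1) / denom)
  iv_estimate("ivw", beta, se, k)
}

#' MR-Egger regression
#'
#' Weighted (`1/se_y^2`) regression of the oriented outcome associations on
#' the exposure associations with a free intercept. The intercept estimates
#' the average directional pleiotropic effect per variant; the slope is the
#' causal estimate, consistent even when all variants are invalid provided
#' instrument strength is independent of the direct effects (InSIDE). Both
#' standard errors use a multiplicative overdispersion factor bounded below
#' by 1.
#'
#' @param summaries a `variant_summary` data.frame (>= 3 rows with spread in
#'   `beta_x`).
#' @return list with elements `intercept` and `slope`, each an
#'   `iv_estimate`.
#' @export
mr_egger <- function(summaries) {
  summaries <- check_summaries(summaries, 3L, "mr_egger")
  warn_weak(summaries)
  if (stats::var(summaries$beta_x) == 0)
    stop("degenerate regression: no spread in beta_x", call. = FALSE)
  w <- 1 / summaries$se_y^2
  fit <- stats::lm(beta_y ~ beta_x, data = summaries, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  # rescale so the residual dispersion factor never shrinks below 1
  adj <- max(sm$sigma, 1) / sm$sigma
  k <- nrow(summaries)
  list(
    intercept = iv_estimate("mr_egger_intercept", co[1, 1], co[1, 2] * adj, k),
    slope = iv_estimate("mr_egger_slope", co[2, 1], co[2, 2] * adj, k)
  )
}

#' Weighted median causal estimate
#'
#' The median of the inverse-variance-weighted empirical distribution of the
#' per-variant ratio estimates `beta_y / beta_x`: ratios are ordered, weights
#' `(beta_x / se_y)^2` normalized to sum one, and the estimate is the linear
#' interpolation of the weighted empirical distribution function at
#' probability 0.5. Consistent when at least half the weight comes from valid
#' instruments. The standard error is a parametric bootstrap, resampling each
#' variant's associations from normal distributions with their standard
#' errors.
#'
#' @param summaries a `variant_summary` data.frame (>= 3 rows).
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed seed for the bootstrap stream.
#' @return an `iv_estimate` with `method_label = "weighted_median"`.
#' @export
weighted_median <- function(summaries, n_boot = 1000L, seed = 1L) {
  summaries <- check_summaries(summaries, 3L, "weighted_median")
  zero <- summaries$beta_x == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " variant(s) with beta_x = 0",
            call. = FALSE)
    summaries <- summaries[!zero, , drop = FALSE]
    if (nrow(summaries) == 0L)
      stop("no variants with nonzero beta_x", call. = FALSE)
  }
  point <- weighted_median_point(summaries$beta_y / summaries$beta_x,
                                 (summaries$beta_x / summaries$se_y)^2)
  boot <- local_seed(seed, {
    k <- nrow(summaries)
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, summaries$beta_x, summaries$se_x)
      by <- stats::rnorm(k, summaries$beta_y, summaries$se_y)
      ok <- bx != 0
      weighted_median_point((by / bx)[ok], (bx / summaries$se_y)[ok]^2)
    }, 0)
  })
  iv_estimate("weighted_median", point, stats::sd(boot), nrow(summaries))
}

# linear interpolation of the weighted ECDF at probability one half;
# cumulative weight of the i-th ordered ratio taken at the bin midpoint
weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Same-trait minus-0.5 correction of the unadjusted estimate
#'
#' When the maternal exposure and offspring outcome are exactly the same
#' trait under an additive linear model, the unadjusted instrument reaches
#' the outcome through the transmitted half of the offspring genotype with
#' slope 0.5 on the standardized scale, so subtracting 0.5 from the
#' unadjusted point estimate (and both confidence bounds) yields an
#' asymptotically unbiased estimate. The correction is a pure shift: the
#' standard error is unchanged. Applicability (same trait, additive linear
#' model, large sample) cannot be verified from the data; the caller's
#' assertion is recorded in the result metadata, not enforced.
#'
#' @param unadjusted an `iv_estimate` from the unadjusted strategy.
#' @param applicability free-text note recording why the caller considers
#'   the same-trait criteria met.
#' @return an `iv_estimate` shifted down by 0.5, with attribute
#'   `"applicability"`.
#' @export
#' @examples
#' est <- iv_estimate <- tsls(rnorm(50), rnorm(50), rnorm(50))
#' minus_half_correction(est)$beta - est$beta   # exactly -0.5
minus_half_correction <- function(unadjusted,
                                  applicability = "asserted by caller") {
  stopifnot(inherits(unadjusted, "iv_estimate"))
  out <- unadjusted
  out$method_label <- paste0(unadjusted$method_label, "_minus_0.5")
  out$beta <- unadjusted$beta - 0.5
  out$ci_low <- unadjusted$ci_low - 0.5
  out$ci_high <- unadjusted$ci_high - 0.5
  attr(out, "applicability") <- applicability
  out
}

#' Read / write variant summary tables
#'
#' Delimited text with fixed columns `variant`, `beta_x`, `se_x`, `beta_y`,
#' `se_y` - an exchange format for downstream summary-statistic tooling.
#'
#' @param summaries a `variant_summary` data.frame.
#' @param path file path (tab-delimited).
#' @return `write_variant_summaries` returns `path` invisibly;
#'   `read_variant_summaries` an oriented `variant_summary`.
#' @export
write_variant_summaries <- function(summaries, path) {
  utils::write.table(
    summaries[c("variant", "beta_x", "se_x", "beta_y", "se_y")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_summaries
#' @export
read_variant_summaries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("variant", "beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(df)))
    stop("summary table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  orient_summaries(df[need])
}
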