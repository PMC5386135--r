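#' Define a simulation scenario for a parent-offspring trio cohort
#'
#' A scenario bundles every generative parameter of one simulation condition:
#' the cohort size, the variant panel, the variance-component parameterization
#' of the maternal exposure and offspring outcome, confounding, assortative
#' mating and horizontal pleiotropy.
#'
#' The model is parameterized on the standardized scale. All allele scores are
#' standardized analytically (binomial haplotype variance), and the path
#' coefficient attached to a variance proportion `v` is `sqrt(v)`, so that a
#' score "explaining v of the variance" contributes exactly `v` to the variance
#' of a unit-variance phenotype. Residual variances of the maternal exposure
#' `X_m` and offspring outcome `Y_o` are solved from the model-implied
#' covariance so that both phenotypes have unit variance; an infeasible budget
#' (negative residual variance) is an error, never a silent rescale.
#'
#' @param n_trios number of mother-father-offspring trios per replicate.
#' @param n_replicates default replicate count used by [run_scenario()].
#' @param n_variants number of independent biallelic variants in the panel.
#' @param effect_allele_freqs effect-allele frequencies, length `n_variants`,
#'   each in (0,1). Default: drawn once, uniformly in \[0.1, 0.9\], from a
#'   stream derived from `seed` (so a scenario is fully determined by its
#'   arguments).
#' @param variant_weights non-negative per-allele score weights, length
#'   `n_variants`. Default: equal weights.
#' @param q_x proportion of maternal-exposure variance explained by the
#'   maternal allele score, in \[0, 1).
#' @param gamma true causal effect of maternal exposure on offspring outcome,
#'   in SD outcome per SD exposure.
#' @param v_o proportion of offspring-outcome variance explained by the
#'   offspring score's direct path, in \[0, 1).
#' @param v_p proportion of offspring-outcome variance explained by the
#'   paternal score's direct path (not mediated by offspring genotype).
#' @param c_x,c_y path coefficients of a shared standard-normal confounder on
#'   exposure and outcome.
#' @param assortment_rho target spousal correlation on the exposure-relevant
#'   phenotype, in (-1, 1). Zero disables assortative mating.
#' @param pleiotropy per-variant direct path coefficients from the centred
#'   maternal dosage to the offspring outcome, length `n_variants`.
#' @param seed root integer seed; replicate streams are derived from
#'   `(seed, replicate_index)` so any replicate is reproducible in isolation.
#'
#' @return An object of class `scenario_config` (a validated list).
#' @seealso [simulate_trio_cohort()], [model_implied_covariance()]
#' @export
#' @examples
#' cfg <- scenario_config(n_trios = 1000, q_x = 0.02, gamma = 0.1, v_o = 0.05)
#' round(model_implied_covariance(cfg)["G_m", "Y_o"], 4)
scenario_config <- function(n_trios = 10000L,
                            n_replicates = 1000L,
                            n_variants = 97L,
                            effect_allele_freqs = NULL,
                            variant_weights = NULL,
                            q_x = 0.02,
                            gamma = 0,
                            v_o = 0,
                            v_p = 0,
                            c_x = 0,
                            c_y = 0,
                            assortment_rho = 0,
                            pleiotropy = NULL,
                            seed = 1L) {
  stopifnot(length(n_trios) == 1L, n_trios >= 1, length(n_variants) == 1L,
            n_variants >= 1, length(n_replicates) == 1L, n_replicates >= 1)
  n_variants <- as.integer(n_variants)

  if (is.null(effect_allele_freqs)) {
    # dedicated stream well away from replicate indices
    effect_allele_freqs <- local_seed(derive_seed(seed, 1073741824), {
      stats::runif(n_variants, 0.1, 0.9)
    })
  }
  if (is.null(variant_weights)) variant_weights <- rep(1, n_variants)
  if (is.null(pleiotropy)) pleiotropy <- rep(0, n_variants)

  cfg <- structure(list(
    n_trios = as.integer(n_trios),
    n_replicates = as.integer(n_replicates),
    n_variants = n_variants,
    effect_allele_freqs = as.numeric(effect_allele_freqs),
    variant_weights = as.numeric(variant_weights),
    q_x = q_x, gamma = gamma, v_o = v_o, v_p = v_p,
    c_x = c_x, c_y = c_y,
    assortment_rho = assortment_rho,
    pleiotropy = as.numeric(pleiotropy),
    seed = as.integer(seed)
  ), class = "scenario_config")

  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (length(effect_allele_freqs) != n_variants)
      stop("effect_allele_freqs must have length n_variants", call. = FALSE)
    if (length(variant_weights) != n_variants)
      stop("variant_weights must have length n_variants", call. = FALSE)
    if (length(pleiotropy) != n_variants)
      stop("pleiotropy must have length n_variants", call. = FALSE)
    if (any(effect_allele_freqs <= 0 | effect_allele_freqs >= 1))
      stop("effect_allele_freqs must lie strictly in (0, 1)", call. = FALSE)
    if (any(variant_weights < 0))
      stop("variant_weights must be non-negative", call. = FALSE)
    if (all(variant_weights == 0))
      stop("at least one variant weight must be positive", call. = FALSE)
    for (nm in c("q_x", "v_o", "v_p")) {
      v <- get(nm)
      if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1)
        stop(sprintf("%s must be a single value in [0, 1)", nm), call. = FALSE)
    }
    if (abs(assortment_rho) >= 1)
      stop("assortment_rho must lie strictly in (-1, 1)", call. = FALSE)
  })
  # solving the residual variances performs the joint feasibility check
  invisible(residual_variances(cfg))
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Trio simulation scenario\n")
  cat(sprintf("  trios: %d  replicates: %d  variants: %d\n",
              x$n_trios, x$n_replicates, x$n_variants))
  cat(sprintf("  q_x = %g  gamma = %g  v_o = %g  v_p = %g\n",
              x$q_x, x$gamma, x$v_o, x$v_p))
  cat(sprintf("  confounding (c_x, c_y) = (%g, %g)  assortment_rho = %g\n",
              x$c_x, x$c_y, x$assortment_rho))
  if (any(x$pleiotropy != 0))
    cat(sprintf("  pleiotropy on %d variant(s)\n", sum(x$pleiotropy != 0)))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

# Analytic moments of the raw allele scores. The full-score (two-haplotype)
# variance is sum(w^2 * 2p(1-p)); half-scores (one haplotype) have half that.
score_moments <- function(cfg) {
  p <- cfg$effect_allele_freqs
  w <- cfg$variant_weights
  list(
    mean_full = sum(w * 2 * p),
    mean_half = sum(w * p),
    sd_full = sqrt(sum(w^2 * 2 * p * (1 - p))),
    sd_half = sqrt(sum(w^2 * p * (1 - p)))
  )
}

# Covariance of the latent standardized regressors
# Z = (G_m, G_o, G_p, G_nt, G_t, C, P) where P is the raw (unstandardized)
# pleiotropy score sum(delta_j * (maternal dosage_j - 2 p_j)). Valid for
# assortment_rho = 0: haplotypes are iid Bernoulli and the only covariances
# are through shared haplotypes.
latent_covariance <- function(cfg) {
  p <- cfg$effect_allele_freqs
  w <- cfg$variant_weights
  delta <- cfg$pleiotropy
  mom <- score_moments(cfg)
  h <- 1 / sqrt(2)                   # corr of a half score with its full score

  v_P <- sum(delta^2 * 2 * p * (1 - p))
  cP_full <- sum(delta * w * 2 * p * (1 - p)) / mom$sd_full  # cov(P, G_m)
  cP_shared <- sum(delta * w * p * (1 - p))                  # one shared haplotype
  cP_o <- cP_shared / mom$sd_full
  cP_half <- cP_shared / mom$sd_half

  nm <- c("G_m", "G_o", "G_p", "G_nt", "G_t", "C", "P")
  S <- diag(c(1, 1, 1, 1, 1, 1, v_P))
  dimnames(S) <- list(nm, nm)
  S["G_m", "G_o"] <- S["G_o", "G_m"] <- 0.5
  S["G_o", "G_p"] <- S["G_p", "G_o"] <- 0.5
  S["G_m", "G_nt"] <- S["G_nt", "G_m"] <- h
  S["G_m", "G_t"] <- S["G_t", "G_m"] <- h
  S["G_o", "G_t"] <- S["G_t", "G_o"] <- h
  S["G_m", "P"] <- S["P", "G_m"] <- cP_full
  S["G_o", "P"] <- S["P", "G_o"] <- cP_o
  S["G_nt", "P"] <- S["P", "G_nt"] <- cP_half
  S["G_t", "P"] <- S["P", "G_t"] <- cP_half
  S
}

# Path weights of X_m and Y_o on the latent regressors.
path_weights <- function(cfg) {
  list(
    w_x = c(G_m = sqrt(cfg$q_x), G_o = 0, G_p = 0, G_nt = 0, G_t = 0,
            C = cfg$c_x, P = 0),
    w_y = c(G_m = 0, G_o = sqrt(cfg$v_o), G_p = sqrt(cfg$v_p), G_nt = 0,
            G_t = 0, C = cfg$c_y, P = 1)
  )
}

#' Residual variances implied by the variance budget
#'
#' Solves the error variances of the maternal exposure and offspring outcome
#' so both have unit variance under the path model. An infeasible budget is a
#' configuration error naming the offending phenotype.
#'
#' @param cfg a [scenario_config()].
#' @return named numeric vector `c(exposure = ..., outcome = ...)`.
#' @export
residual_variances <- function(cfg) {
  S <- latent_covariance(cfg)
  pw <- path_weights(cfg)
  s2_x <- 1 - drop(pw$w_x %*% S %*% pw$w_x)
  if (s2_x < -1e-12)
    stop("infeasible variance budget for the maternal exposure: ",
         "q_x + c_x^2 exceeds 1", call. = FALSE)
  s2_x <- max(s2_x, 0)
  u <- cfg$gamma * pw$w_x + pw$w_y     # total coefficient of Y_o on Z
  s2_y <- 1 - drop(u %*% S %*% u) - cfg$gamma^2 * s2_x
  if (s2_y < -1e-12)
    stop("infeasible variance budget for the offspring outcome: ",
         "direct paths, confounding and the causal path jointly exceed ",
         "unit variance", call. = FALSE)
  c(exposure = s2_x, outcome = max(s2_y, 0))
}

#' Model-implied covariance of scores and phenotypes
#'
#' Closed-form covariance of the standardized scores and phenotypes under the
#' path model with no assortative mating, obtained by path tracing. Serves as
#' the analytic oracle for the simulator (the empirical cohort covariance
#' converges to it) and for expected estimates; for example the entry
#' `(G_m, G_o)` is 0.5, the parent-offspring score correlation, and
#' `(G_m, Y_o) = gamma*sqrt(q_x) + 0.5*sqrt(v_o)` absent pleiotropy.
#'
#' @param cfg a [scenario_config()] with `assortment_rho = 0`.
#' @return covariance matrix over
#'   `G_m, G_o, G_p, G_nt, G_t, C, X_m, Y_o`, with the solved residual
#'   variances attached as attribute `"residual_variances"`.
#' @export
model_implied_covariance <- function(cfg) {
  if (cfg$assortment_rho != 0)
    stop("closed-form covariance is only available without assortative mating",
         call. = FALSE)
  S <- latent_covariance(cfg)
  pw <- path_weights(cfg)
  s2 <- residual_variances(cfg)
  u <- cfg$gamma * pw$w_x + pw$w_y

  covZX <- drop(S %*% pw$w_x)
  covZY <- drop(S %*% u)
  nm <- c("G_m", "G_o", "G_p", "G_nt", "G_t", "C", "X_m", "Y_o")
  out <- matrix(0, 8, 8, dimnames = list(nm, nm))
  out[1:6, 1:6] <- S[1:6, 1:6]
  out[1:6, "X_m"] <- out["X_m", 1:6] <- covZX[1:6]
  out[1:6, "Y_o"] <- out["Y_o", 1:6] <- covZY[1:6]
  out["X_m", "X_m"] <- 1
  out["Y_o", "Y_o"] <- 1
  out["X_m", "Y_o"] <- out["Y_o", "X_m"] <-
    drop(pw$w_x %*% S %*% u) + cfg$gamma * s2[["exposure"]]
  attr(out, "residual_variances") <- s2
  out
}

#' Write / read a scenario configuration as flat text
#'
#' Serializes a scenario to a `key = value` file; vector fields are stored as
#' comma-separated lists. The round trip reproduces the scenario exactly.
#'
#' @param cfg a [scenario_config()].
#' @param path file path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` returns a `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  fmt <- function(v) paste(format(v, digits = 17, trim = TRUE), collapse = ",")
  keys <- setdiff(names(cfg), NULL)
  lines <- vapply(keys, function(k) sprintf("%s = %s", k, fmt(cfg[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(strsplit(trimws(x[2]), ",")[[1]])),
    vapply(kv, function(x) trimws(x[1]), "")
  )
  do.call(scenario_config, vals)
}
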