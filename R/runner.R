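#' Run all replicates of one simulation scenario
#'
#' Simulates `n_replicates` independent cohorts from `cfg` and applies the
#' requested estimation strategies to each. Replicates that fail (e.g. a
#' degenerate design) are logged and excluded from aggregation, with counts
#' reported. Deterministic given the scenario seed: replicate `i` always uses
#' the stream derived from `(seed, i)`.
#'
#' @param cfg a [scenario_config()].
#' @param n_replicates overrides `cfg$n_replicates` when given.
#' @param strategies passed to [estimate_all_strategies()].
#' @return data.frame with one row per replicate x strategy: `replicate`,
#'   `method`, `beta`, `se`, `first_stage_F`; failed replicate indices in
#'   attribute `"failed"`.
#' @export
run_scenario <- function(cfg, n_replicates = NULL,
                         strategies = c("unadjusted", "offspring_adjusted",
                                        "offspring_paternal_adjusted",
                                        "nontransmitted", "transmitted")) {
  R <- n_replicates %||% cfg$n_replicates
  rows <- vector("list", R)
  failed <- integer(0)
  for (i in seq_len(R)) {
    est <- tryCatch({
      cohort <- simulate_trio_cohort(cfg, i - 1L)
      estimate_all_strategies(cohort, strategies = strategies)
    }, error = function(e) e)
    if (inherits(est, "error")) {
      failed <- c(failed, i - 1L)
      next
    }
    df <- as.data.frame(est)
    df$replicate <- i - 1L
    rows[[i]] <- df
  }
  if (length(failed))
    warning(sprintf("%d of %d replicates failed and were excluded",
                    length(failed), R), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("scenario produced zero completed replicates", call. = FALSE)
  attr(out, "failed") <- failed
  out
}

#' Aggregate replicate estimates into a scenario summary
#'
#' Per strategy: the mean point estimate, the empirical SD of estimates
#' across replicates, the mean model-based SE, bias (`mean_beta - gamma`,
#' exactly), power (fraction of replicates whose 95% CI excludes zero) and
#' coverage (fraction whose 95% CI contains `gamma`).
#'
#' @param estimates data.frame from [run_scenario()] (columns `method`,
#'   `beta`, `se`, `replicate`).
#' @param gamma the scenario's true causal effect.
#' @return data.frame of class `scenario_summary`, one row per strategy.
#' @export
summarize_replicates <- function(estimates, gamma) {
  if (is.null(estimates) || nrow(estimates) == 0L)
    stop("no replicate estimates to summarize", call. = FALSE)
  out <- lapply(split(estimates, estimates$method), function(d) {
    lo <- d$beta - 1.96 * d$se
    hi <- d$beta + 1.96 * d$se
    data.frame(
      method = d$method[1],
      mean_beta = mean(d$beta),
      empirical_sd = stats::sd(d$beta),
      mean_model_se = mean(d$se),
      bias = mean(d$beta) - gamma,
      power = mean(lo > 0 | hi < 0),
      coverage = mean(lo <= gamma & gamma <= hi),
      n_replicates_completed = nrow(d)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' Run a grid of simulation scenarios
#'
#' Orchestrates the replicate x scenario grid: each configuration is
#' simulated, estimated under all strategies and aggregated with
#' [summarize_replicates()]. Deterministic given the per-scenario seeds.
#'
#' @param configs list of [scenario_config()] objects (e.g. from
#'   [illustrative_scenarios()] or [scenario_grid()]).
#' @param n_replicates optional override applied to every scenario.
#' @param strategies passed through to [run_scenario()].
#' @param verbose print progress per scenario.
#' @return data.frame with one row per scenario x strategy; scenario
#'   parameters (`gamma`, `q_x`, `v_o`, `v_p`, `c_x`, `c_y`, `n_trios`,
#'   `seed`) prepended to the summary columns.
#' @export
run_grid <- function(configs, n_replicates = NULL, strategies = NULL,
                     verbose = FALSE) {
  stopifnot(length(configs) >= 1L)
  strategies <- strategies %||% c("unadjusted", "offspring_adjusted",
                                  "offspring_paternal_adjusted",
                                  "nontransmitted", "transmitted")
  out <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    if (verbose)
      message(sprintf("scenario %d/%d: gamma=%g v_o=%g v_p=%g",
                      i, length(configs), cfg$gamma, cfg$v_o, cfg$v_p))
    est <- tryCatch(
      run_scenario(cfg, n_replicates = n_replicates, strategies = strategies),
      error = function(e)
        stop(sprintf("scenario %d (gamma=%g, v_o=%g, v_p=%g) failed: %s",
                     i, cfg$gamma, cfg$v_o, cfg$v_p, conditionMessage(e)),
             call. = FALSE))
    s <- summarize_replicates(est, cfg$gamma)
    cbind(data.frame(scenario = i, gamma = cfg$gamma, q_x = cfg$q_x,
                     v_o = cfg$v_o, v_p = cfg$v_p, c_x = cfg$c_x,
                     c_y = cfg$c_y, n_trios = cfg$n_trios, seed = cfg$seed),
          s)
  })
  out <- do.call(rbind, out)
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' Build a factorial grid of scenario configurations
#'
#' Crosses the supplied parameter vectors; every other parameter is shared.
#' Each cell gets its own seed derived from `seed` so cells are independent
#' but individually reproducible.
#'
#' @param gamma,v_o,v_p,q_x,c_x,c_y parameter vectors to cross.
#' @param n_trios,n_replicates,n_variants,seed shared settings.
#' @param ... further arguments passed to [scenario_config()].
#' @return list of `scenario_config` objects.
#' @export
scenario_grid <- function(gamma = c(0, 0.10), v_o = c(0, 0.01, 0.05),
                          v_p = c(0, 0.01, 0.05), q_x = 0.02,
                          c_x = 0, c_y = 0, n_trios = 10000L,
                          n_replicates = 1000L, n_variants = 97L,
                          seed = 1L, ...) {
  cells <- expand.grid(gamma = gamma, v_o = v_o, v_p = v_p, q_x = q_x,
                       c_x = c_x, c_y = c_y)
  lapply(seq_len(nrow(cells)), function(i) {
    scenario_config(n_trios = n_trios, n_replicates = n_replicates,
                    n_variants = n_variants,
                    gamma = cells$gamma[i], v_o = cells$v_o[i],
                    v_p = cells$v_p[i], q_x = cells$q_x[i],
                    c_x = cells$c_x[i], c_y = cells$c_y[i],
                    seed = derive_seed(seed, i), ...)
  })
}

#' Shipped scenario presets
#'
#' `illustrative_scenarios()` is the illustrative 2 x 3 x 3 grid (true effect 0 or
#' 0.10; offspring and paternal direct paths each explaining 0, 1 or 5% of
#' outcome variance; instrument explaining 2% of exposure variance; zero net
#' confounding). `same_trait_scenarios()` is the same-trait sensitivity preset
#' (offspring path 2% - matching the instrument's 2% on the exposure, as
#' when mother and offspring share the trait - paternal path 1%), under the
#' null and under a true effect of 0.10.
#'
#' @param n_replicates,n_trios,seed,... passed to [scenario_grid()].
#' @return list of `scenario_config` objects.
#' @export
illustrative_scenarios <- function(n_replicates = 1000L, n_trios = 10000L,
                             seed = 1L, ...) {
  scenario_grid(gamma = c(0, 0.10), v_o = c(0, 0.01, 0.05),
                v_p = c(0, 0.01, 0.05), q_x = 0.02,
                n_replicates = n_replicates, n_trios = n_trios,
                seed = seed, ...)
}

#' @rdname illustrative_scenarios
#' @export
same_trait_scenarios <- function(n_replicates = 1000L, n_trios = 10000L,
                             seed = 1L, ...) {
  scenario_grid(gamma = c(0, 0.10), v_o = 0.02, v_p = 0.01, q_x = 0.02,
                n_replicates = n_replicates, n_trios = n_trios,
                seed = seed, ...)
}

#' Write grid summaries and a run manifest
#'
#' Writes one tab-delimited summary table (strategies pivoted into the
#' four-column layout: no adjustment, offspring adjustment only, offspring
#' and paternal adjustment, maternal non-transmitted alleles, plus the
#' transmitted comparator) and a manifest recording seed, package and R
#' versions, and a timestamp. Re-running with the same seed reproduces the
#' tables byte-for-byte; only the manifest timestamp differs.
#'
#' @param summaries output of [run_grid()].
#' @param dir destination directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(summaries, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create report directory: ", dir, call. = FALSE)
  paths <- character(0)
  if (is.null(summaries) || nrow(as.data.frame(summaries)) == 0L) {
    warning("empty summary collection: writing manifest only", call. = FALSE)
  } else {
    wide <- pivot_summary(summaries)
    tab <- file.path(dir, "scenario_summaries.tsv")
    utils::write.table(wide, tab, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- tab
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(
    sprintf("package = triomr %s",
            as.character(utils::packageVersion("triomr"))),
    sprintf("r_version = %s", R.version.string),
    sprintf("seeds = %s",
            paste(unique(as.data.frame(summaries)$seed), collapse = ",")),
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), manifest)
  invisible(c(paths, manifest))
}

strategy_order <- c("unadjusted", "offspring_adjusted",
                    "offspring_paternal_adjusted", "nontransmitted",
                    "transmitted")

pivot_summary <- function(summaries) {
  df <- as.data.frame(summaries)
  keys <- c("scenario", "gamma", "q_x", "v_o", "v_p", "c_x", "c_y",
            "n_trios", "seed")
  keys <- intersect(keys, names(df))
  out <- unique(df[keys])
  for (mth in intersect(strategy_order, unique(df$method))) {
    sub <- df[df$method == mth, c(keys, "mean_beta", "empirical_sd")]
    names(sub)[names(sub) == "mean_beta"] <- paste0(mth, "_beta")
    names(sub)[names(sub) == "empirical_sd"] <- paste0(mth, "_sd")
    out <- merge(out, sub, by = keys, sort = FALSE)
  }
  out[order(out$scenario %||% seq_len(nrow(out))), ]
}
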