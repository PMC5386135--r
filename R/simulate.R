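#' Simulate one parent-offspring trio cohort
#'
#' Generates a cohort of mother-father-offspring trios under the path model of
#' [scenario_config()]. Parental haplotypes are independent Bernoulli draws at
#' each variant; the offspring genotype is the sum of one labelled transmitted
#' haplotype from each parent, so transmission ground truth is carried in the
#' cohort. The maternal exposure is driven by the standardized maternal allele
#' score and a shared confounder; the offspring outcome by the exposure
#' (causal path `gamma`), direct offspring and paternal score paths, the
#' confounder, and any per-variant pleiotropy.
#'
#' All scores are standardized analytically: a full (two-haplotype) score by
#' `sqrt(sum(w^2 * 2p(1-p)))`, a transmitted- or non-transmitted-only
#' haplotype score by its own analytic SD, so unit variance holds by
#' construction rather than by in-sample rescaling.
#'
#' @param cfg a [scenario_config()].
#' @param replicate_index replicate number (>= 0); combined with `cfg$seed`
#'   to derive an independent, reproducible random stream per replicate.
#' @return An object of class `trio_cohort`: haplotype matrices
#'   (`maternal_transmitted`, `maternal_nontransmitted`,
#'   `paternal_transmitted`, `paternal_nontransmitted`, all n x m in {0,1}),
#'   dosage matrices (`maternal_genotype`, `paternal_genotype`,
#'   `offspring_genotype`), standardized scores `G_m`, `G_o`, `G_p`, `G_t`,
#'   `G_nt`, the confounder `C`, phenotypes `X_m`, `Y_o`, and the generating
#'   `config`.
#' @seealso [simulate_with_assortment()], [estimate_all_strategies()]
#' @export
#' @examples
#' cohort <- simulate_trio_cohort(scenario_config(n_trios = 500, seed = 7))
#' cor(cohort$G_m, cohort$G_o)   # about 0.5
simulate_trio_cohort <- function(cfg, replicate_index = 0L) {
  stopifnot(inherits(cfg, "scenario_config"), replicate_index >= 0)
  s2 <- residual_variances(cfg)

  local_seed(derive_seed(cfg$seed, replicate_index), {
    n <- cfg$n_trios
    m <- cfg$n_variants
    p <- cfg$effect_allele_freqs
    w <- cfg$variant_weights
    prow <- rep(p, each = n)

    # double storage from the start: avoids integer->double coercion copies
    # in the repeated matrix products (a measurable cost at grid scale)
    hap <- function() matrix(as.double(stats::rbinom(n * m, 1L, prow)), n, m)
    mt <- hap(); mnt <- hap(); pt <- hap(); pnt <- hap()

    mom <- score_moments(cfg)
    C <- stats::rnorm(n)
    s_mt <- drop(mt %*% w); s_mnt <- drop(mnt %*% w)
    G_m <- (s_mt + s_mnt - mom$mean_full) / mom$sd_full
    X_m <- sqrt(cfg$q_x) * G_m + cfg$c_x * C +
      sqrt(s2[["exposure"]]) * stats::rnorm(n)

    if (cfg$assortment_rho != 0) {
      # Rank-based spousal coupling on noisy copies of the exposure-relevant
      # phenotype: pair the i-th ranked mother (on a latent normal correlated
      # rho with the father's latent) with the correspondingly ranked father.
      G_p_std <- (drop((pt + pnt) %*% w) - mom$mean_full) / mom$sd_full
      X_p <- sqrt(cfg$q_x) * G_p_std + sqrt(1 - cfg$q_x) * stats::rnorm(n)
      u <- stats::rnorm(n)
      v <- cfg$assortment_rho * u +
        sqrt(1 - cfg$assortment_rho^2) * stats::rnorm(n)
      idx_m <- order(X_m)[rank(u, ties.method = "first")]
      idx_f <- order(X_p)[rank(v, ties.method = "first")]
      mt <- mt[idx_m, , drop = FALSE]; mnt <- mnt[idx_m, , drop = FALSE]
      pt <- pt[idx_f, , drop = FALSE]; pnt <- pnt[idx_f, , drop = FALSE]
      C <- C[idx_m]; X_m <- X_m[idx_m]; G_m <- G_m[idx_m]
      s_mt <- drop(mt %*% w); s_mnt <- drop(mnt %*% w)
    }

    offspring <- mt + pt
    s_pt <- drop(pt %*% w); s_pnt <- drop(pnt %*% w)
    G_o <- (s_mt + s_pt - mom$mean_full) / mom$sd_full
    G_p <- (s_pt + s_pnt - mom$mean_full) / mom$sd_full
    G_t <- (s_mt - mom$mean_half) / mom$sd_half
    G_nt <- (s_mnt - mom$mean_half) / mom$sd_half

    pleio <- if (any(cfg$pleiotropy != 0)) {
      drop(mt %*% cfg$pleiotropy) + drop(mnt %*% cfg$pleiotropy) -
        sum(cfg$pleiotropy * 2 * p)
    } else 0
    Y_o <- cfg$gamma * X_m + sqrt(cfg$v_o) * G_o + sqrt(cfg$v_p) * G_p +
      cfg$c_y * C + pleio + sqrt(s2[["outcome"]]) * stats::rnorm(n)

    structure(list(
      maternal_transmitted = mt, maternal_nontransmitted = mnt,
      paternal_transmitted = pt, paternal_nontransmitted = pnt,
      maternal_genotype = mt + mnt, paternal_genotype = pt + pnt,
      offspring_genotype = offspring,
      G_m = G_m, G_o = G_o, G_p = G_p, G_t = G_t, G_nt = G_nt,
      C = C, X_m = X_m, Y_o = Y_o,
      config = cfg, replicate_index = as.integer(replicate_index)
    ), class = "trio_cohort")
  })
}

#' Simulate a trio cohort under assortative mating
#'
#' Identical to [simulate_trio_cohort()] except that spouses are paired
#' non-randomly on an exposure-relevant phenotype. With `assortment_rho = 0`
#' this is exactly [simulate_trio_cohort()] (same seed path). Assortment with
#' `q_x > 0` induces a positive spousal score correlation `cor(G_m, G_p)`,
#' which biases the non-transmitted-allele strategy away from the truth.
#'
#' @inheritParams simulate_trio_cohort
#' @return a `trio_cohort`.
#' @export
simulate_with_assortment <- function(cfg, replicate_index = 0L) {
  simulate_trio_cohort(cfg, replicate_index)
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("Trio cohort: %d trios x %d variants (replicate %d)\n",
              x$config$n_trios, x$config$n_variants, x$replicate_index))
  cat(sprintf("  cor(G_m, G_o) = %.3f   cor(X_m, Y_o) = %.3f\n",
              stats::cor(x$G_m, x$G_o), stats::cor(x$X_m, x$Y_o)))
  invisible(x)
}

#' Export / import a trio cohort as delimited text
#'
#' Writes one row per trio: standardized scores, confounder, phenotypes, then
#' per-variant dosage columns `m_<j>`, `f_<j>`, `o_<j>` (effect-allele counts,
#' stated in the header comment). `read_cohort` reconstructs a cohort usable
#' by every estimator; haplotype-level ground truth is not representable in
#' the dosage export and is absent from a read-back cohort.
#'
#' @param cohort a `trio_cohort`.
#' @param path file path (tab-delimited text).
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   `trio_cohort` (without haplotype truth).
#' @export
write_cohort <- function(cohort, path) {
  m <- cohort$config$n_variants
  df <- data.frame(
    G_m = cohort$G_m, G_o = cohort$G_o, G_p = cohort$G_p,
    G_t = cohort$G_t, G_nt = cohort$G_nt,
    C = cohort$C, X_m = cohort$X_m, Y_o = cohort$Y_o
  )
  geno <- cbind(cohort$maternal_genotype, cohort$paternal_genotype,
                cohort$offspring_genotype)
  colnames(geno) <- c(sprintf("m_%d", seq_len(m)), sprintf("f_%d", seq_len(m)),
                      sprintf("o_%d", seq_len(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# triomr cohort export: genotype columns are effect-allele dosage counts",
    sprintf("# effect_allele_freqs = %s",
            paste(format(cohort$config$effect_allele_freqs, digits = 17,
                         trim = TRUE), collapse = ",")),
    sprintf("# variant_weights = %s",
            paste(format(cohort$config$variant_weights, digits = 17,
                         trim = TRUE), collapse = ","))
  ), con)
  utils::write.table(cbind(df, geno), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 10L)
  header <- header[startsWith(header, "#")]
  get_vec <- function(key) {
    line <- grep(paste0("# ", key), header, value = TRUE, fixed = TRUE)
    if (!length(line)) return(NULL)
    as.numeric(strsplit(sub(".*= *", "", line[1]), ",")[[1]])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  m <- sum(startsWith(names(df), "m_"))
  pick <- function(prefix) as.matrix(df[sprintf("%s_%d", prefix, seq_len(m))])
  freqs <- get_vec("effect_allele_freqs") %||% rep(0.5, m)
  weights <- get_vec("variant_weights") %||% rep(1, m)
  cfg <- scenario_config(n_trios = nrow(df), n_variants = m,
                         effect_allele_freqs = freqs,
                         variant_weights = weights)
  structure(list(
    maternal_genotype = pick("m"), paternal_genotype = pick("f"),
    offspring_genotype = pick("o"),
    G_m = df$G_m, G_o = df$G_o, G_p = df$G_p, G_t = df$G_t, G_nt = df$G_nt,
    C = df$C, X_m = df$X_m, Y_o = df$Y_o,
    config = cfg, replicate_index = NA_integer_
  ), class = "trio_cohort")
}
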