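#' Resolve maternal allele transmission at one biallelic variant
#'
#' Determines which maternal allele was transmitted to the offspring from
#' unphased dosages. The rule is deterministic in the three dosages: a
#' homozygous mother is trivially resolved; a heterozygous mother with a
#' homozygous offspring is resolved; a mother-offspring double heterozygote is
#' resolved only when the father's dosage is homozygous (the offspring's
#' paternal allele is then known and the maternal allele is deduced), and is
#' otherwise `ambiguous`. An offspring dosage incompatible with the parental
#' dosages yields status `mendelian_error` (a status, not an exception).
#'
#' @param mother,offspring dosages in \{0, 1, 2\} (effect-allele counts).
#' @param father dosage in \{0, 1, 2\}, or `NA` when the father is untyped.
#' @return list with `status` (one of `"resolved"`, `"ambiguous"`,
#'   `"mendelian_error"`), `transmitted` and `nontransmitted` maternal alleles
#'   in \{0, 1\} (`NA` unless resolved).
#' @export
#' @examples
#' resolve_transmission(2, 1)            # resolved: transmitted 1, kept 1
#' resolve_transmission(1, 1)$status     # ambiguous without the father
#' resolve_transmission(1, 1, father = 2)# father homozygous: resolved
resolve_transmission <- function(mother, offspring, father = NA) {
  stopifnot(mother %in% 0:2, offspring %in% 0:2,
            is.na(father) || father %in% 0:2)
  am <- switch(as.character(mother), "0" = 0L, "1" = 0:1, "2" = 1L)
  ap <- if (is.na(father)) 0:1
        else switch(as.character(father), "0" = 0L, "1" = 0:1, "2" = 1L)
  grid <- expand.grid(am = am, ap = ap)
  ok <- grid[grid$am + grid$ap == offspring, , drop = FALSE]
  if (nrow(ok) == 0L)
    return(list(status = "mendelian_error",
                transmitted = NA_integer_, nontransmitted = NA_integer_))
  tx <- unique(ok$am)
  if (length(tx) > 1L)
    return(list(status = "ambiguous",
                transmitted = NA_integer_, nontransmitted = NA_integer_))
  list(status = "resolved", transmitted = as.integer(tx),
       nontransmitted = as.integer(mother - tx))
}

# 3 x 3 x 4 lookup (mother, offspring, father with index 4 = missing),
# built once from the scalar rule so matrix resolution stays a pure function
# of the three dosages.
transmission_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      status <- array("", dim = c(3, 3, 4))
      tx <- array(NA_integer_, dim = c(3, 3, 4))
      for (mo in 0:2) for (of in 0:2) for (fi in 1:4) {
        fa <- if (fi == 4L) NA else fi - 1L
        r <- resolve_transmission(mo, of, fa)
        status[mo + 1, of + 1, fi] <- r$status
        tx[mo + 1, of + 1, fi] <- r$transmitted
      }
      tab <<- list(status = status, transmitted = tx)
    }
    tab
  }
})

#' Resolve transmission across a cohort of trios
#'
#' Vectorized application of [resolve_transmission()] to dosage matrices
#' (trios in rows, variants in columns). Accepts the simulator's cohort
#' export format or any delimited dosage table read into matrices.
#'
#' @param mother,offspring integer matrices of dosages in \{0,1,2\}.
#' @param father matching matrix, or `NULL` when fathers are untyped.
#' @return object of class `transmission_calls`: `status` (character matrix),
#'   `transmitted`, `nontransmitted` (integer matrices, `NA` unless resolved).
#' @export
resolve_transmission_table <- function(mother, offspring, father = NULL) {
  mother <- as.matrix(mother); offspring <- as.matrix(offspring)
  stopifnot(all(dim(mother) == dim(offspring)))
  fi <- if (is.null(father)) 4L else {
    father <- as.matrix(father)
    stopifnot(all(dim(father) == dim(mother)))
    father + 1L
  }
  tab <- transmission_table()
  idx <- cbind(as.vector(mother) + 1L, as.vector(offspring) + 1L,
               as.vector(fi))
  status <- matrix(tab$status[idx], nrow(mother), ncol(mother))
  transmitted <- matrix(tab$transmitted[idx], nrow(mother), ncol(mother))
  structure(list(status = status, transmitted = transmitted,
                 nontransmitted = ifelse(is.na(transmitted), NA_integer_,
                                         mother - transmitted)),
            class = "transmission_calls")
}

#' Ground-truth transmission calls from a simulated cohort
#'
#' The simulator labels each haplotype, so every trio-variant cell is
#' resolved exactly. Mirrors the assumption that the pattern of transmission
#' is known precisely, as with dense genome-wide trio data.
#'
#' @param cohort a `trio_cohort` produced by [simulate_trio_cohort()].
#' @return a `transmission_calls` object with all cells resolved.
#' @export
transmission_truth <- function(cohort) {
  stopifnot(!is.null(cohort$maternal_transmitted))
  structure(list(
    status = matrix("resolved", nrow(cohort$maternal_transmitted),
                    ncol(cohort$maternal_transmitted)),
    transmitted = cohort$maternal_transmitted,
    nontransmitted = cohort$maternal_nontransmitted
  ), class = "transmission_calls")
}

#' Build non-transmitted (and transmitted) haplotype scores
#'
#' Constructs standardized maternal haplotype scores from resolved calls
#' only. Ambiguous cells are excluded rather than imputed: imputing them at
#' the allele frequency would shrink the instrument back toward the full
#' maternal score and re-introduce the transmitted component the
#' non-transmitted design exists to remove. Each trio's score is centred and
#' scaled by the analytic moments of its own resolved variant set
#' (`sum(w^2 p(1-p))` over resolved variants), so retained scores have unit
#' variance whatever the resolution pattern. Trios resolved at fewer than
#' `min_resolved_frac` of the weighted panel are dropped (`NA` scores).
#'
#' @param calls a `transmission_calls` object.
#' @param weights,freqs per-variant score weights and effect-allele
#'   frequencies.
#' @param min_resolved_frac minimum fraction of panel weight (by `w^2 p(1-p)`
#'   variance contribution) that must be resolved for a trio to be scored.
#' @param max_mendel_rate run fails if the Mendelian-error cell rate exceeds
#'   this (errors are reported, never silently dropped).
#' @return list with standardized `G_nt` and `G_t` (NA for dropped trios),
#'   `report` (per-variant resolved fraction and Mendelian error count), and
#'   `n_dropped`.
#' @export
build_nontransmitted_score <- function(calls, weights, freqs,
                                       min_resolved_frac = 0.5,
                                       max_mendel_rate = 0.01) {
  stopifnot(inherits(calls, "transmission_calls"),
            length(weights) == ncol(calls$status),
            length(freqs) == ncol(calls$status))
  mend <- calls$status == "mendelian_error"
  rate <- mean(mend)
  if (rate > max_mendel_rate)
    stop(sprintf("Mendelian error rate %.2f%% exceeds the %.2f%% threshold",
                 100 * rate, 100 * max_mendel_rate), call. = FALSE)
  resolved <- calls$status == "resolved"
  if (!any(resolved))
    stop("empty instrument: no trio-variant cell could be resolved",
         call. = FALSE)

  vcontrib <- weights^2 * freqs * (1 - freqs)   # per-variant haplotype variance
  R <- resolved * 1
  denom2 <- drop(R %*% vcontrib)                # per-trio resolved variance
  frac <- denom2 / sum(vcontrib)
  keep <- frac >= min_resolved_frac & denom2 > 0

  score <- function(h) {
    h0 <- h; h0[!resolved] <- 0L
    num <- drop(h0 %*% weights) - drop(R %*% (weights * freqs))
    out <- num / sqrt(denom2)
    out[!keep] <- NA_real_
    out
  }
  list(
    G_nt = score(calls$nontransmitted),
    G_t = score(calls$transmitted),
    report = data.frame(
      variant = seq_along(weights),
      resolved_frac = colMeans(resolved),
      mendelian_errors = colSums(mend)
    ),
    n_dropped = sum(!keep)
  )
}

#' Write a per-variant transmission resolution report
#'
#' @param calls a `transmission_calls` object.
#' @param path destination (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_resolution_report <- function(calls, path) {
  df <- data.frame(
    variant = seq_len(ncol(calls$status)),
    resolved_frac = colMeans(calls$status == "resolved"),
    ambiguous_frac = colMeans(calls$status == "ambiguous"),
    mendelian_errors = colSums(calls$status == "mendelian_error")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
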