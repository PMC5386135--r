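# the enumeration oracle oracle_resolve() lives in helper-oracles.R

test_that("resolution matches brute-force enumeration over all combinations", {
  for (mo in 0:2) for (of in 0:2) for (fa in c(0:2, NA)) {
    got <- resolve_transmission(mo, of, fa)
    want <- oracle_resolve(mo, of, fa)
    label <- sprintf("m=%d o=%d f=%s", mo, of, fa)
    if (is.character(want)) {
      expect_identical(got$status, want, label = label)
      expect_true(is.na(got$transmitted), label = label)
    } else {
      expect_identical(got$status, "resolved", label = label)
      expect_identical(got$transmitted, want$transmitted, label = label)
      expect_identical(got$nontransmitted, as.integer(mo - want$transmitted),
                       label = label)
    }
  }
})

test_that("documented single-call behaviour", {
  expect_identical(resolve_transmission(2, 1)[c("transmitted", "nontransmitted")],
                   list(transmitted = 1L, nontransmitted = 1L))
  expect_identical(resolve_transmission(1, 0)$transmitted, 0L)
  expect_identical(resolve_transmission(1, 1)$status, "ambiguous")
  expect_identical(resolve_transmission(1, 1, father = 1)$status, "ambiguous")
  r <- resolve_transmission(1, 1, father = 2)
  expect_identical(r[c("status", "transmitted", "nontransmitted")],
                   list(status = "resolved", transmitted = 0L,
                        nontransmitted = 1L))
  expect_identical(resolve_transmission(0, 2, 0)$status, "mendelian_error")
})

test_that("matrix resolution is the scalar rule applied cellwise", {
  cfg <- mid_config(seed = 47L)
  co <- simulate_trio_cohort(cfg)
  calls <- resolve_transmission_table(co$maternal_genotype,
                                      co$offspring_genotype,
                                      co$paternal_genotype)
  idx <- cbind(sample(nrow(calls$status), 50), sample(ncol(calls$status), 50,
                                                      replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ref <- resolve_transmission(co$maternal_genotype[i, j],
                                co$offspring_genotype[i, j],
                                co$paternal_genotype[i, j])
    expect_identical(calls$status[i, j], ref$status)
  }
  # no resolved call ever contradicts the simulator's ground truth
  res <- calls$status == "resolved"
  expect_true(all(calls$transmitted[res] == co$maternal_transmitted[res]))
  expect_true(all(calls$nontransmitted[res] ==
                    co$maternal_nontransmitted[res]))
  # there are no Mendelian errors in simulator output
  expect_false(any(calls$status == "mendelian_error"))
})

test_that("ambiguity rate matches the enumeration oracle", {
  # probability that (mother, offspring, father) are all heterozygous, from
  # the Mendelian haplotype distribution at allele frequency p
  p <- 0.5
  prob_amb <- 0
  for (mt in 0:1) for (mnt in 0:1) for (pt in 0:1) for (pnt in 0:1) {
    pr <- prod(ifelse(c(mt, mnt, pt, pnt) == 1, p, 1 - p))
    if (mt + mnt == 1 && pt + pnt == 1 && mt + pt == 1)
      prob_amb <- prob_amb + pr
  }
  cfg <- scenario_config(n_trios = 40000L, n_variants = 2L,
                         effect_allele_freqs = c(0.5, 0.5), seed = 53L)
  co <- simulate_trio_cohort(cfg)
  calls <- resolve_transmission_table(co$maternal_genotype,
                                      co$offspring_genotype,
                                      co$paternal_genotype)
  amb <- mean(calls$status == "ambiguous")
  expect_equal(amb, prob_amb, tolerance = 0.03)
  # without fathers every mother-offspring double heterozygote is ambiguous
  calls_nf <- resolve_transmission_table(co$maternal_genotype,
                                         co$offspring_genotype)
  both_het <- co$maternal_genotype == 1 & co$offspring_genotype == 1
  expect_identical(calls_nf$status == "ambiguous", both_het)
})

test_that("ground-truth calls reproduce the simulator scores exactly", {
  cfg <- mid_config(seed = 59L)
  co <- simulate_trio_cohort(cfg)
  sc <- build_nontransmitted_score(transmission_truth(co),
                                   cfg$variant_weights,
                                   cfg$effect_allele_freqs)
  expect_equal(sc$G_nt, co$G_nt, tolerance = 1e-12)
  expect_equal(sc$G_t, co$G_t, tolerance = 1e-12)
  expect_equal(sc$n_dropped, 0L)
  expect_true(all(sc$report$resolved_frac == 1))
})

test_that("scores from dosage-resolved calls are valid instruments", {
  cfg <- scenario_config(n_trios = 8000L, n_variants = 12L, q_x = 0.05,
                         gamma = 0.1, v_o = 0.05, seed = 61L)
  co <- simulate_trio_cohort(cfg)
  calls <- resolve_transmission_table(co$maternal_genotype,
                                      co$offspring_genotype,
                                      co$paternal_genotype)
  sc <- build_nontransmitted_score(calls, cfg$variant_weights,
                                   cfg$effect_allele_freqs)
  kept <- !is.na(sc$G_nt)
  expect_equal(sd(sc$G_nt[kept]), 1, tolerance = 0.05)
  expect_gt(cor(sc$G_nt[kept], co$G_nt[kept]), 0.9)
  # still uncorrelated with the offspring score
  expect_lt(abs(cor(sc$G_nt[kept], co$G_o[kept])), 0.05)
})

test_that("degenerate cohorts are rejected", {
  n <- 50
  m1 <- matrix(1L, n, 2)  # every mother and offspring heterozygous
  calls <- resolve_transmission_table(m1, m1)
  expect_error(build_nontransmitted_score(calls, c(1, 1), c(0.5, 0.5)),
               "empty instrument")
  # Mendelian errors above the threshold fail the run with the rate named
  off <- matrix(0L, n, 2); mother <- matrix(2L, n, 2)
  bad <- resolve_transmission_table(mother, off)
  expect_error(build_nontransmitted_score(bad, c(1, 1), c(0.5, 0.5)),
               "Mendelian error rate")
})

test_that("resolution report is written as delimited text", {
  co <- simulate_trio_cohort(tiny_config(seed = 67L))
  calls <- resolve_transmission_table(co$maternal_genotype,
                                      co$offspring_genotype)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resolution_report(calls, path)
  rep <- read.delim(path)
  expect_identical(names(rep), c("variant", "resolved_frac",
                                 "ambiguous_frac", "mendelian_errors"))
  expect_equal(nrow(rep), ncol(calls$status))
})
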