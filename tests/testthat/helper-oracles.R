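# Brute-force transmission oracle: enumerate every haplotype assignment
# compatible with the three dosages and read off the possible maternal
# transmitted alleles. Shares nothing with the package's rule table.
oracle_resolve <- function(mother, offspring, father) {
  hap_pairs <- function(d) {
    if (is.na(d)) return(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
    switch(as.character(d), "0" = list(c(0, 0)),
           "1" = list(c(0, 1), c(1, 0)), "2" = list(c(1, 1)))
  }
  transmitted <- integer(0)
  for (mh in hap_pairs(mother)) for (fh in hap_pairs(father)) {
    for (mi in 1:2) for (fi in 1:2) {
      if (mh[mi] + fh[fi] == offspring)
        transmitted <- union(transmitted, mh[mi])
    }
  }
  if (length(transmitted) == 0) "mendelian_error"
  else if (length(transmitted) == 2) "ambiguous"
  else list(status = "resolved", transmitted = as.integer(transmitted))
}
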