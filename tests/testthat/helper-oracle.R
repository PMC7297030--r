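# Independent brute-force oracle for pool allele-frequency expectations.
# Enumerates every gamete a parent can produce as an explicit (marker allele,
# locus-1 allele[, locus-2 allele]) tuple and crosses them exhaustively;
# written deliberately apart from the package's enumeration code.

oracle_gametes <- function(pair, n_loci) {
  # complete marker-locus1 linkage: haplotype 1 carries the recessive allele
  g <- data.frame(marker = pair, locus1 = c("rec", "dom"),
                  stringsAsFactors = FALSE)
  if (n_loci == 2L) {
    g <- merge(g, data.frame(locus2 = c("rec", "dom")), by = NULL)
  }
  g
}

oracle_pool_af <- function(seed_pair, pollen_pair, n_loci) {
  gs <- oracle_gametes(seed_pair, n_loci)
  gp <- oracle_gametes(pollen_pair, n_loci)
  total_rec <- 0L; total_dom <- 0L
  var_rec <- 0L; var_dom <- 0L
  for (i in seq_len(nrow(gs))) {
    for (j in seq_len(nrow(gp))) {
      recessive <- gs$locus1[i] == "rec" && gp$locus1[j] == "rec" &&
        (n_loci == 1L || (gs$locus2[i] == "rec" && gp$locus2[j] == "rec"))
      v <- (gs$marker[i] == "V") + (gp$marker[j] == "V")
      if (recessive) {
        total_rec <- total_rec + 2L; var_rec <- var_rec + v
      } else {
        total_dom <- total_dom + 2L; var_dom <- var_dom + v
      }
    }
  }
  c(af_recessive = 100 * var_rec / total_rec,
    af_dominant = 100 * var_dom / total_dom)
}
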