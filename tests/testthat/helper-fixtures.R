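# Shared fixture builders: everything is generated in code, no data files.

# minimal geographic panel with n populations on a rough north-south line
toy_geo <- function(n, labels = LETTERS[seq_len(n)]) {
  geo_panel(labels,
            latitude = seq(40, 60, length.out = n),
            longitude = seq(0, 20, length.out = n))
}

# a small multi-population simulation config with quiet defaults
toy_config <- function(n_pops = 3, n_per_pop = 30, n_snps = 200,
                       fst = rep(0.01, n_pops), seed = 1, ...) {
  sim_config(n_populations = n_pops,
             samples_per_pop = rep(n_per_pop, n_pops),
             n_snps = n_snps, fst_per_pop = fst,
             geo = toy_geo(n_pops), seed = seed, ...)
}

# hand-built genotype dataset from a dosage matrix
toy_dataset <- function(dosages, populations = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(populations)) populations <- rep("P1", n)
  snps <- data.frame(snp_id = sprintf("m%03d", seq_len(m)),
                     chromosome = rep("1", m),
                     position_bp = seq_len(m) * 1000L,
                     allele_ref = rep("A", m), allele_alt = rep("G", m),
                     stringsAsFactors = FALSE)
  geno_dataset(dosages,
               sample_ids = sprintf("s%02d", seq_len(n)),
               populations = populations, snps = snps)
}

# all permutations of 1..n as rows (independent of the package's internal)
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(ifelse(sub >= k, sub + 1L, sub), nrow(sub)))))
}

# random symmetric zero-diagonal distance matrix
rand_dist <- function(n, seed) {
  set.seed(seed)
  D <- matrix(runif(n * n), n)
  D <- D + t(D); diag(D) <- 0
  D
}
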