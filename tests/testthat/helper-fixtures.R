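# Shared fixtures, all generated in code.

toy_map <- function(n_loci, n_chrom = 1, len = 100) {
  sim_map(n_loci = n_loci, n_chrom = n_chrom, chrom_length_cM = len)
}

# Tiny deterministic diploid panel: 2 homozygous + 2 phased heterozygous
# parents on 6 loci / 2 chromosomes.
toy_phased_panel <- function() {
  map <- toy_map(6, 2, 50)
  h <- list(
    P1 = rbind(c(1, 1, 0, 1, 0, 1), c(1, 1, 0, 1, 0, 1)),
    P2 = rbind(c(0, 0, 1, 0, 1, 0), c(0, 0, 1, 0, 1, 0)),
    P3 = rbind(c(1, 0, 1, 1, 1, 0), c(0, 1, 1, 0, 0, 0)),
    P4 = rbind(c(1, 1, 0, 0, 1, 1), c(0, 0, 0, 1, 1, 0)))
  dos <- t(vapply(h, colSums, numeric(6)))
  colnames(dos) <- map$marker
  parent_panel(dos, map, ploidy = 2, haplotypes = h,
               subpop = c("a", "a", "b", "b"))
}

# Small LD-rich DH panel (two pools).
ld_panel <- function(n_loci = 60, lines = 12, seed = 7) {
  make_diploid_dataset(toy_map(n_loci, 2, 100), n_lines_per_pool = lines,
                       n_hap_per_pool = 4 * lines, seed = seed)
}

ld_panel4 <- function(n_loci = 60, n_genotypes = 20, seed = 5) {
  make_tetraploid_dataset(toy_map(n_loci, 2, 100), n_genotypes = n_genotypes,
                          n_founder_hap = 4 * n_genotypes, seed = seed)
}

cvm4 <- function() class_value_map(4, dominance = dominance_score_polysomic(4))

# Monte-Carlo mean/sd of genotypic values of simulated progeny.
sim_truth <- function(panel, pair, scheme, effects, n, cvm = NULL, seed = 11) {
  dos <- simulate_progeny(panel, pair, scheme, n, seed = seed)
  gv <- genotypic_value(dos, effects, cvm, ploidy = panel$ploidy)
  c(mean = mean(gv), sd = sd(gv), se_mean = sd(gv) / sqrt(n))
}
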