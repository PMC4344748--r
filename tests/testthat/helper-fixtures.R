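# Shared fixtures, built once per test run and memoised.

the_fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(the_fixtures[[key]])) the_fixtures[[key]] <- builder()
  the_fixtures[[key]]
}

# A small but realistic simulated panel: 2 chromosomes x 20 cM, 300 sites
# each, 200 haplotypes.
fixture_panel <- function() {
  memo("panel", function() {
    sim_haplotype_panel(
      n_haplotypes = 200, map = genetic_map(2, 20, 2e7),
      sites_per_chrom = 300, seed = 424242, max_generations = 40
    )
  })
}

# One long chromosome for LD-decay checks.
fixture_ld_panel <- function() {
  memo("ld_panel", function() {
    sim_haplotype_panel(
      n_haplotypes = 200, map = genetic_map(1, 100, 1e8),
      sites_per_chrom = 1500, seed = 777, max_generations = 80
    )
  })
}

# A hand-built panel: 6 haplotypes x 6 sites on 2 chromosomes, exact
# frequencies by construction.
toy_panel <- function() {
  hap <- rbind(
    c(1L, 0L, 0L, 1L, 1L, 0L),
    c(1L, 1L, 0L, 0L, 1L, 0L),
    c(0L, 1L, 0L, 1L, 0L, 1L),
    c(0L, 0L, 1L, 0L, 0L, 1L),
    c(1L, 0L, 1L, 1L, 1L, 0L),
    c(0L, 1L, 1L, 0L, 0L, 1L)
  )
  sites <- data.frame(
    chrom = c(1L, 1L, 1L, 2L, 2L, 2L),
    pos_cM = c(2, 5, 9, 1, 4, 8),
    pos_bp = c(2e6, 5e6, 9e6, 1e6, 4e6, 8e6)
  )
  haplotype_panel(hap, sites, genetic_map(2, 10, 1e7))
}

# Mendelian consistency: every progeny allele must be carried by the matching
# parent at that site. Returns TRUE when all sites of all progeny check out.
mendelian_ok <- function(gen1, gen2) {
  sire_rows <- match(gen2$pedigree$sire, gen1$pedigree$id)
  dam_rows <- match(gen2$pedigree$dam, gen1$pedigree$id)
  pat_ok <- gen2$paternal == gen1$maternal[sire_rows, , drop = FALSE] |
    gen2$paternal == gen1$paternal[sire_rows, , drop = FALSE]
  mat_ok <- gen2$maternal == gen1$maternal[dam_rows, , drop = FALSE] |
    gen2$maternal == gen1$paternal[dam_rows, , drop = FALSE]
  all(pat_ok) && all(mat_ok)
}

# A fast scenario configuration for engine tests.
tiny_config <- function() {
  sim_config(
    n_chromosomes = 2, chr_length_cM = 20, chr_length_bp = 2e7,
    sites_per_chrom = 200, n_haplotypes = 100, max_generations = 15,
    qtl_per_chrom = 20, n_sires = 2, dams_per_sire = 3
  )
}
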