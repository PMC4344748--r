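#' Sample marker or QTL sites from a panel
#'
#' Draws an equal number of segregating sites from each chromosome, uniformly
#' without replacement, optionally excluding sites already committed elsewhere
#' (for example QTL when sampling markers). This mirrors the study design in
#' which marker panels of 3 K to 300 K SNPs and 9000 QTL were drawn with equal
#' numbers per chromosome.
#'
#' @param panel A [haplotype_panel()].
#' @param n_per_chromosome Sites to draw from each chromosome.
#' @param exclude Integer vector of site indices that must not be drawn.
#' @param seed Integer seed (or NULL).
#'
#' @return Sorted integer vector of site indices into `panel$sites`
#'   (length `n_per_chromosome * n_chromosomes`).
#' @examples
#' p <- sim_haplotype_panel(20, genetic_map(2, 20, 2e7),
#'   sites_per_chrom = 50, seed = 1, max_generations = 10
#' )
#' qtl <- sample_sites(p, 10, seed = 2)
#' markers <- sample_sites(p, 20, exclude = qtl, seed = 3)
#' length(intersect(qtl, markers)) # 0
#' @export
sample_sites <- function(panel, n_per_chromosome, exclude = integer(), seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_per_chromosome <- check_count(n_per_chromosome, "n_per_chromosome")
  check_seed(seed)
  exclude <- as.integer(exclude)

  by_chrom <- split(panel$sites$site, panel$sites$chrom)
  with_seed_maybe(seed, {
    picks <- purrr::imap(by_chrom, function(sites, chrom) {
      eligible <- setdiff(sites, exclude)
      if (length(eligible) < n_per_chromosome) {
        abort(sprintf(
          "Chromosome %s has only %d eligible site(s); %d requested.",
          chrom, length(eligible), n_per_chromosome
        ))
      }
      sample(eligible, n_per_chromosome)
    })
    sort(unlist(picks, use.names = FALSE))
  })
}
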