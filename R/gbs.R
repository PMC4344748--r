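#' Probability of calling a heterozygote from n reads
#'
#' With error-free reads, a heterozygous genotype is recognised only when both
#' alleles are observed among the `n` reads of a locus, which happens with
#' probability 1 - 2/2^n; each homozygous genotype is (mis)called with
#' probability 1/2^n. The probability is 0 at n = 1, 0.5 at n = 2, 0.75 at
#' n = 3, 0.875 at n = 4, and so on.
#'
#' @param n_reads Integer vector of read counts, all >= 1.
#' @return Numeric vector of probabilities.
#' @examples
#' het_call_probability(1:4)
#' @export
het_call_probability <- function(n_reads) {
  if (length(n_reads) == 0L || anyNA(n_reads) || any(n_reads < 1) ||
      any(n_reads != trunc(n_reads))) {
    abort("`n_reads` must be integers >= 1 (the call is undefined at 0 reads).")
  }
  1 - 2 / 2^n_reads
}

#' Sample per-locus read depths
#'
#' Read counts are independent Poisson(x) across loci and individuals, the
#' standard model for genome-wide sequencing coverage x.
#'
#' @param x Mean genome-wide read depth per locus (>= 0).
#' @param n_individuals,n_loci Matrix dimensions.
#' @param seed Integer seed (or NULL).
#' @return Integer matrix (individuals x loci) of class `read_depth_matrix`
#'   with attribute `x`.
#' @export
sample_read_depths <- function(x, n_individuals, n_loci, seed = NULL) {
  check_number(x, "x", min = 0)
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_loci <- check_count(n_loci, "n_loci")
  check_seed(seed)
  with_seed_maybe(seed, {
    d <- matrix(rpois(n_individuals * n_loci, x), n_individuals, n_loci)
    structure(d, x = x, class = c("read_depth_matrix", class(d)))
  })
}

#' Call genotypes from error-free reads
#'
#' Implements the discrete calling rule: zero reads give a missing call; one
#' or more reads at a homozygous locus always give the correct homozygote; at
#' a heterozygous locus the heterozygote is called with probability
#' 1 - 2/2^n and each homozygote with probability 1/2^n (all reads happening
#' to carry the same allele).
#'
#' @param true_dosage Integer vector of true genotypes in {0, 1, 2}.
#' @param n_reads Integer vector of read counts (>= 0), recycled against
#'   `true_dosage`.
#' @param seed Integer seed (or NULL to consume the current RNG stream).
#' @return Integer vector of called dosages, with `NA` for missing (no-read)
#'   entries.
#' @examples
#' call_genotype(rep(1, 10), rep(2, 10), seed = 1)
#' @export
call_genotype <- function(true_dosage, n_reads, seed = NULL) {
  if (anyNA(true_dosage) || !all(true_dosage %in% 0:2)) {
    abort("`true_dosage` entries must be 0, 1, or 2.")
  }
  if (anyNA(n_reads) || any(n_reads < 0) || any(n_reads != trunc(n_reads))) {
    abort("`n_reads` entries must be non-negative integers.")
  }
  check_seed(seed)
  n <- max(length(true_dosage), length(n_reads))
  true_dosage <- rep_len(as.integer(true_dosage), n)
  n_reads <- rep_len(as.integer(n_reads), n)
  with_seed_maybe(seed, {
    out <- true_dosage            # homozygotes: exact call when covered
    out[n_reads == 0L] <- NA_integer_
    het <- which(true_dosage == 1L & n_reads >= 1L)
    if (length(het) > 0L) {
      u <- runif(length(het))
      p_hom <- 2^(-n_reads[het])  # each homozygote
      out[het] <- ifelse(u < p_hom, 0L, ifelse(u < 2 * p_hom, 2L, 1L))
    }
    out
  })
}

new_genotype_matrix <- function(dosages, state, freqs, x, realized_depth,
                                sites = NULL) {
  structure(
    list(
      dosages = dosages, state = state, freqs = freqs, x = x,
      realized_depth = realized_depth, sites = sites
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individual(s) x %d marker(s); platform %s\n",
    nrow(x$dosages), ncol(x$dosages),
    if (is.infinite(x$x %||% Inf)) "SNP array (error-free)"
    else sprintf("GBS at x = %g (realized %.3g)", x$x, x$realized_depth)
  ))
  tab <- table(factor(x$state,
    levels = c("array", "gbs_called", "missing_filled")
  ))
  cat("  call states:",
      paste(sprintf("%s %.3g%%", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of entries filled with the mean dosage
#' @param geno A `genotype_matrix`.
#' @return Proportion of missing-filled entries.
#' @export
fraction_filled <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  mean(geno$state == "missing_filled")
}

#' Simulate GBS genotyping of a set of markers
#'
#' Composes [sample_read_depths()] and [call_genotype()]: per individual and
#' marker the read depth is Poisson(`x`); covered loci receive a discrete
#' 0/1/2 call under the error-free calling rule; loci with no reads are filled
#' with twice the allele frequency of the allele coded 1 ("mean dosage"),
#' using the base-population frequencies which are taken as known.
#'
#' @param pop A `gs_population`.
#' @param marker_sites Integer site indices to genotype.
#' @param x Mean read depth per locus.
#' @param freqs Allele-1 frequencies used for mean filling, one per marker;
#'   defaults to the base-panel frequencies stored in the population's site
#'   table.
#' @param seed Integer seed (or NULL).
#' @return A `genotype_matrix`: list with `dosages` (individuals x markers,
#'   values in \[0, 2\]), `state` (character matrix: `"gbs_called"` or
#'   `"missing_filled"`), `freqs`, `x`, and the realized mean depth.
#' @export
genotype_gbs <- function(pop, marker_sites, x, freqs = NULL, seed = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  check_number(x, "x", min = 0)
  check_seed(seed)
  marker_sites <- as.integer(marker_sites)
  freqs <- freqs %||% pop$sites$base_freq[marker_sites]
  if (length(freqs) != length(marker_sites)) {
    abort("`freqs` must supply one frequency per marker site.")
  }
  true <- dosage(pop, marker_sites)
  with_seed_maybe(seed, {
    depths <- matrix(
      rpois(length(true), x), nrow(true), ncol(true)
    )
    calls <- matrix(
      call_genotype(as.vector(true), as.vector(depths)),
      nrow(true), ncol(true)
    )
    state <- matrix("gbs_called", nrow(true), ncol(true))
    miss <- is.na(calls)
    state[miss] <- "missing_filled"
    fill <- matrix(2 * freqs, nrow(true), ncol(true), byrow = TRUE)
    dos <- ifelse(miss, fill, calls)
    rownames(dos) <- pop$pedigree$id
    new_genotype_matrix(
      dos, state, freqs, x, mean(depths), sites = marker_sites
    )
  })
}

#' Error-free SNP-array genotyping
#'
#' Returns the true dosages at the marker sites: array genotypes are called
#' from the sequence directly, without error or missingness.
#'
#' @inheritParams genotype_gbs
#' @return A `genotype_matrix` with all states `"array"` and `x = Inf`.
#' @export
genotype_array <- function(pop, marker_sites, freqs = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  marker_sites <- as.integer(marker_sites)
  freqs <- freqs %||% pop$sites$base_freq[marker_sites]
  d <- dosage(pop, marker_sites)
  state <- matrix("array", nrow(d), ncol(d))
  new_genotype_matrix(d, state, freqs, Inf, Inf, sites = marker_sites)
}
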