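#' Sample a polygenic trait architecture
#'
#' Draws QTL as an equal-per-chromosome random sample of segregating sites
#' (300 per chromosome, 9000 in total, at full scale) and assigns each an
#' allele-substitution effect from Normal(0, sd = 1/sqrt(n_qtl)). Variance
#' components are attached later, when phenotypes are simulated against a
#' reference cohort.
#'
#' @param panel A [haplotype_panel()].
#' @param per_chromosome QTL per chromosome (default 300).
#' @param exclude Site indices that may not become QTL.
#' @param seed Integer seed (or NULL).
#' @return An object of class `trait_architecture`: a list with `qtl` (a
#'   tibble with columns `site`, `chrom`, `base_freq`, `effect`), `n_qtl`, and
#'   `effect_sd` (the 1/sqrt(n_qtl) sampling standard deviation).
#' @export
sample_trait_architecture <- function(panel, per_chromosome = 300,
                                      exclude = integer(), seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  check_seed(seed)
  with_seed_maybe(seed, {
    sites <- sample_sites(panel, per_chromosome, exclude = exclude)
    n_qtl <- length(sites)
    effect_sd <- 1 / sqrt(n_qtl)
    qtl <- panel$sites[sites, c("site", "chrom", "base_freq")]
    qtl$effect <- rnorm(n_qtl, 0, effect_sd)
    structure(
      list(qtl = qtl, n_qtl = n_qtl, effect_sd = effect_sd),
      class = "trait_architecture"
    )
  })
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "<trait_architecture> %d QTL; effect sd parameter %.5f (sample sd %.5f)\n",
    x$n_qtl, x$effect_sd, sd(x$qtl$effect)
  ))
  invisible(x)
}

#' True breeding values
#'
#' TBV of individual i is the sum over QTL of the allele-substitution effect
#' times the true allele-1 dosage (0/1/2).
#'
#' @param pop A `gs_population`.
#' @param arch A [sample_trait_architecture()] result.
#' @return Named numeric vector of TBV (names are individual ids).
#' @export
true_breeding_values <- function(pop, arch) {
  stopifnot(inherits(pop, "gs_population"), inherits(arch, "trait_architecture"))
  d <- dosage(pop, arch$qtl$site)
  tbv <- drop(d %*% arch$qtl$effect)
  names(tbv) <- pop$pedigree$id
  tbv
}

#' Simulate phenotypes at a target heritability
#'
#' The genetic variance is taken as the realized variance of TBV in the
#' supplied cohort, the residual variance is set to
#' `sigma_g2 * (1 - h2) / h2`, and phenotypes are TBV plus independent normal
#' residuals, so the realized heritability matches `h2` up to sampling error.
#'
#' @param tbv Numeric vector of true breeding values (optionally named by id).
#' @param h2 Narrow-sense heritability in (0, 1); default 0.25.
#' @param seed Integer seed (or NULL).
#' @return An object of class `trait_phenotypes`: list with `data` (tibble
#'   `id`, `tbv`, `y`), `h2`, `sigma_g2`, `sigma_e2`.
#' @examples
#' ph <- simulate_phenotypes(rnorm(100), h2 = 0.25, seed = 1)
#' ph$sigma_e2 / ph$sigma_g2 # = 3 at h2 = 0.25
#' @export
simulate_phenotypes <- function(tbv, h2 = 0.25, seed = NULL) {
  if (!is.numeric(tbv) || length(tbv) < 2L) {
    abort("`tbv` must be a numeric vector of length >= 2.")
  }
  check_number(h2, "h2", min = 0, strict = TRUE)
  if (h2 >= 1) abort("`h2` must be strictly below 1.")
  check_seed(seed)
  sigma_g2 <- var(tbv)
  if (sigma_g2 <= 0) {
    abort("TBV variance is zero; heritability is undefined for this cohort.")
  }
  sigma_e2 <- sigma_g2 * (1 - h2) / h2
  with_seed_maybe(seed, {
    y <- tbv + rnorm(length(tbv), 0, sqrt(sigma_e2))
    structure(
      list(
        data = tibble::tibble(
          id = names(tbv) %||% as.character(seq_along(tbv)),
          tbv = unname(tbv), y = unname(y)
        ),
        h2 = h2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2
      ),
      class = "trait_phenotypes"
    )
  })
}

#' @export
print.trait_phenotypes <- function(x, ...) {
  cat(sprintf(
    "<trait_phenotypes> n = %d; h2 = %.3f; sigma_g2 = %.4g; sigma_e2 = %.4g\n",
    nrow(x$data), x$h2, x$sigma_g2, x$sigma_e2
  ))
  invisible(x)
}
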