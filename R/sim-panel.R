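#' Simulate a base haplotype panel (forward Wright-Fisher)
#'
#' Generates base-population haplotypes with a rare-variant-skewed allele
#' frequency spectrum and linkage disequilibrium that decays with genetic
#' distance, standing in for a full coalescent simulation at desk scale.
#'
#' The generator seeds a diploid population at mutation-drift equilibrium
#' (derived-allele counts drawn proportional to 1/i, sites independent) and
#' then propagates it through the most recent `max_generations` generations
#' of the effective-size trajectory by discrete Wright-Fisher reproduction
#' with recombination and infinite-sites mutation. New mutations enter as
#' singletons at a rate calibrated so the equilibrium segregating-site count
#' matches `sites_per_chrom * oversample`, keeping the spectrum stationary
#' while drift and recombination build linkage disequilibrium; deep history
#' beyond `max_generations` is summarised by the equilibrium initialisation.
#'
#' Two rescalings keep the simulation honest at reduced size:
#' * the census at each generation is `Ne(t) / scale`, floored at
#'   `min_diploids` and at `n_haplotypes / 2` so the terminal generation can
#'   supply the panel without re-using lineages;
#' * the per-meiosis crossover rate is adjusted each generation so the
#'   population-scaled recombination rate matches the unscaled history,
#'   `morgans_used = morgans_true * Ne(t) / (scale * N_used)`; with
#'   `scale = 1` and the census tracking Ne exactly this reduces to the plain
#'   1%-per-cM map.
#'
#' @param n_haplotypes Even number (>= 4) of base haplotypes to return.
#' @param map A [genetic_map()].
#' @param ne An [ne_schedule()]; the default is the declining cattle-like
#'   history (43 500 down to 100).
#' @param sites_per_chrom Exact number of segregating sites per chromosome in
#'   the returned panel.
#' @param seed Integer seed for reproducibility (or NULL for the global RNG).
#' @param scale Divisor applied to Ne and multiplier on anchor times
#'   (default 1: the recent history of the default schedule is small enough
#'   to simulate at face value).
#' @param max_generations Number of forward generations simulated (default
#'   100, enough to build substantial short-range LD on top of the
#'   equilibrium spectrum). 0 returns the equilibrium-spectrum panel itself
#'   (no LD).
#' @param oversample Equilibrium margin of simulated over requested sites
#'   (default 1.4), absorbing sampling losses when the panel is drawn.
#' @param min_diploids Floor on the simulated census (default 50).
#'
#' @return A [haplotype_panel()] with exactly `sites_per_chrom` segregating
#'   sites on each chromosome.
#' @examples
#' p <- sim_haplotype_panel(
#'   n_haplotypes = 40, map = genetic_map(2, 20, 2e7),
#'   sites_per_chrom = 100, seed = 1, max_generations = 20
#' )
#' p
#' @export
sim_haplotype_panel <- function(n_haplotypes,
                                map = genetic_map(),
                                ne = ne_schedule(),
                                sites_per_chrom = 2000,
                                seed = NULL,
                                scale = 1,
                                max_generations = 100,
                                oversample = 1.4,
                                min_diploids = 50) {
  n_haplotypes <- check_count(n_haplotypes, "n_haplotypes", min = 4L)
  if (n_haplotypes %% 2L != 0L) abort("`n_haplotypes` must be even.")
  sites_per_chrom <- check_count(sites_per_chrom, "sites_per_chrom")
  stopifnot(inherits(map, "genetic_map"), inherits(ne, "ne_schedule"))
  check_number(scale, "scale", min = 0, strict = TRUE)
  max_generations <- check_count(max_generations, "max_generations", min = 0L)
  check_number(oversample, "oversample", min = 1)
  min_diploids <- check_count(min_diploids, "min_diploids", min = 2L)
  check_seed(seed)

  n_floor <- max(min_diploids, as.integer(ceiling(n_haplotypes / 2)))
  ne_true <- function(g) ne_at(ne, g * scale * ne$generation_interval)
  size_at <- function(g) {
    pmax(as.integer(round(ne_true(g) / scale)), n_floor)
  }

  with_seed_maybe(seed, {
    chroms <- purrr::pmap(
      list(map$chrom, map$length_cM, map$length_bp),
      function(chrom, len_cM, len_bp) {
        res <- sim_panel_chromosome(
          len_cM, len_bp, sites_per_chrom, oversample,
          size_at, ne_true, max_generations, n_haplotypes, scale
        )
        res$sites$chrom <- chrom
        res
      }
    )
    hap <- do.call(cbind, purrr::map(chroms, "haplotypes"))
    sites <- purrr::list_rbind(purrr::map(chroms, "sites"))
    haplotype_panel(hap, sites, map)
  })
}

# One chromosome of the forward simulation; returns haplotypes + site table.
sim_panel_chromosome <- function(len_cM, len_bp, target, oversample,
                                 size_at, ne_true, gens, n_haplotypes, scale) {
  n0 <- size_at(gens)
  # Sites monomorphic within the sampled panel rows are unusable; inflate the
  # simulated site count by the expected survival of an equilibrium-spectrum
  # site under row subsampling (hypergeometric), on top of `oversample`.
  n_term_hap <- 2L * size_at(0L)
  surv <- if (n_haplotypes < n_term_hap) {
    i <- seq_len(n_term_hap - 1L)
    pr <- (1 / i) / sum(1 / i)
    p_mono <- exp(lchoose(n_term_hap - i, n_haplotypes) -
                    lchoose(n_term_hap, n_haplotypes)) +
      exp(lchoose(i, n_haplotypes) - lchoose(n_term_hap, n_haplotypes))
    sum(pr * (1 - p_mono))
  } else {
    1
  }
  s_eq <- target * oversample / surv
  # Mutational input: a population of census N holds theta * harmonic(2N - 1)
  # segregating sites at equilibrium, so the per-generation singleton input
  # that keeps ~s_eq sites segregating is s_eq / (2 * harmonic(2N - 1)),
  # recalibrated at each generation's census.
  harm <- function(k) log(k) + 0.5772156649 + 1 / (2 * k)

  s0 <- as.integer(ceiling(s_eq))
  pos_cM <- sort(runif(s0, 0, len_cM))
  h <- init_equilibrium_haplotypes(2L * n0, s0)
  morgans_true <- len_cM / 100

  if (gens > 0L) {
    for (g in seq(gens - 1L, 0L)) {
      n_child <- size_at(g)
      morgans_used <- morgans_true * ne_true(g) / scale / n_child
      h <- wf_generation(h, n_child, pos_cM, len_cM, morgans_used)
      # Drop sites lost or fixed; without back mutation they are inert, and
      # per-generation pruning keeps the matrix small.
      f <- colMeans(h)
      alive <- f > 0 & f < 1
      if (!all(alive)) {
        h <- h[, alive, drop = FALSE]
        pos_cM <- pos_cM[alive]
      }
      # New mutations: singletons at fresh positions on random haplotypes.
      # Columns are appended unsorted (recombination only needs per-site
      # positions); one sort at the end restores map order.
      n_new <- rpois(1L, s_eq / (2 * harm(2L * n_child - 1L)))
      if (n_new > 0L) {
        newcols <- matrix(0L, nrow(h), n_new)
        newcols[cbind(sample.int(nrow(h), n_new, replace = TRUE),
                      seq_len(n_new))] <- 1L
        h <- cbind(h, newcols)
        pos_cM <- c(pos_cM, runif(n_new, 0, len_cM))
      }
    }
    ord <- order(pos_cM)
    h <- h[, ord, drop = FALSE]
    pos_cM <- pos_cM[ord]
  }

  # Draw the requested panel and keep exactly `target` segregating sites.
  keep_rows <- sample.int(nrow(h), n_haplotypes)
  h <- h[keep_rows, , drop = FALSE]
  freq <- colMeans(h)
  seg <- which(freq > 0 & freq < 1)
  if (length(seg) < target) {
    abort(sprintf(
      paste0(
        "Only %d segregating site(s) in the sampled panel (need %d); ",
        "increase `oversample`."
      ),
      length(seg), target
    ))
  }
  keep <- sort(sample(seg, target))
  list(
    haplotypes = h[, keep, drop = FALSE],
    sites = tibble::tibble(
      pos_cM = pos_cM[keep], pos_bp = pos_cM[keep] / len_cM * len_bp
    )
  )
}

# Standing variation at neutral equilibrium: derived-allele count i drawn with
# probability proportional to 1/i (i = 1..2N-1), carriers a uniform subset of
# haplotypes, sites independent (linkage equilibrium).
init_equilibrium_haplotypes <- function(n_hap, n_sites) {
  i <- seq_len(n_hap - 1L)
  counts <- sample(i, n_sites, replace = TRUE, prob = 1 / i)
  h <- matrix(0L, nrow = n_hap, ncol = n_sites)
  for (s in seq_len(n_sites)) {
    h[sample.int(n_hap, counts[s]), s] <- 1L
  }
  h
}

# One Wright-Fisher generation: 2 * n_child gametes, each a Poisson-crossover
# mosaic of two uniformly drawn parental haplotypes.
wf_generation <- function(h, n_child, pos_cM, len_cM, morgans) {
  n_gam <- 2L * n_child
  n_par_hap <- nrow(h)
  # Parent individual = an unordered pair of haplotype rows; with random
  # mating and random pairing each generation this is equivalent to drawing
  # two haplotype rows per gamete.
  p1 <- sample.int(n_par_hap, n_gam, replace = TRUE)
  p2 <- sample.int(n_par_hap, n_gam, replace = TRUE)
  k <- rpois(n_gam, morgans)
  start <- sample.int(2L, n_gam, replace = TRUE) - 1L

  out <- matrix(0L, nrow = n_gam, ncol = ncol(h))
  plain <- k == 0L
  if (any(plain)) {
    src <- ifelse(start[plain] == 0L, p1[plain], p2[plain])
    out[plain, ] <- h[src, , drop = FALSE]
  }
  for (g in which(!plain)) {
    bks <- sort(runif(k[g], 0, len_cM))
    sel <- (findInterval(pos_cM, bks) + start[g]) %% 2L
    row <- h[p1[g], ]
    swap <- sel == 1L
    row[swap] <- h[p2[g], swap]
    out[g, ] <- row
  }
  out
}
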