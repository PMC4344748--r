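#' Mating design for the two-generation pedigree
#'
#' Describes how sires and dams are mated to produce the second generation:
#' `n_sires` sires each mated to `dams_per_sire` dams, with `n_progeny`
#' progeny allocated across the matings as evenly as divisibility allows
#' (remainders go to the first matings).
#'
#' @param n_sires Number of sires (default 25).
#' @param dams_per_sire Dams mated to each sire (default 20).
#' @param n_progeny Total progeny in the second generation.
#' @return An object of class `mating_design`.
#' @examples
#' mating_design(2, 2, 9)$allocation
#' @export
mating_design <- function(n_sires = 25, dams_per_sire = 20, n_progeny) {
  n_sires <- check_count(n_sires, "n_sires")
  dams_per_sire <- check_count(dams_per_sire, "dams_per_sire")
  n_progeny <- check_count(n_progeny, "n_progeny")
  n_matings <- n_sires * dams_per_sire
  alloc <- rep(n_progeny %/% n_matings, n_matings)
  extra <- n_progeny %% n_matings
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  structure(
    list(
      n_sires = n_sires, dams_per_sire = dams_per_sire,
      n_dams = n_matings, n_progeny = n_progeny, allocation = alloc
    ),
    class = "mating_design"
  )
}

new_population <- function(pedigree, maternal, paternal, sites, map) {
  storage.mode(maternal) <- "integer"
  storage.mode(paternal) <- "integer"
  stopifnot(
    nrow(pedigree) == nrow(maternal), nrow(pedigree) == nrow(paternal),
    ncol(maternal) == nrow(sites), ncol(paternal) == nrow(sites)
  )
  structure(
    list(
      pedigree = tibble::as_tibble(pedigree),
      maternal = maternal, paternal = paternal,
      sites = sites, map = map
    ),
    class = "gs_population"
  )
}

#' @export
print.gs_population <- function(x, ...) {
  gens <- table(x$pedigree$generation)
  cat(sprintf(
    "<gs_population> %d individual(s) [%s] over %d site(s)\n",
    nrow(x$pedigree),
    paste(sprintf("gen %s: %d", names(gens), gens), collapse = ", "),
    ncol(x$maternal)
  ))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `gs_population`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) {
  stopifnot(inherits(pop, "gs_population"))
  nrow(pop$pedigree)
}

#' Found the first generation from a base haplotype panel
#'
#' Each founder's two haplotypes per chromosome are drawn uniformly, with
#' replacement across individuals, from the panel's haplotype pool. Sexes are
#' assigned alternately (M, F, M, ...) by default, guaranteeing a predictable
#' supply of parents; set `sex = "random"` for Bernoulli(0.5) sexes.
#'
#' @param panel A [haplotype_panel()].
#' @param n Number of founders.
#' @param seed Integer seed (or NULL).
#' @param sex `"alternating"` (default) or `"random"`.
#' @return A `gs_population` whose pedigree has columns `id`, `sex`, `sire`,
#'   `dam` (both NA for founders), and `generation` (1).
#' @export
make_generation1 <- function(panel, n, seed = NULL,
                             sex = c("alternating", "random")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- check_count(n, "n")
  sex <- match.arg(sex)
  check_seed(seed)
  n_hap <- nrow(panel$haplotypes)
  n_sites <- ncol(panel$haplotypes)
  chrom_of <- panel$sites$chrom

  with_seed_maybe(seed, {
    maternal <- matrix(0L, n, n_sites)
    paternal <- matrix(0L, n, n_sites)
    for (ch in unique(chrom_of)) {
      cols <- which(chrom_of == ch)
      maternal[, cols] <- panel$haplotypes[
        sample.int(n_hap, n, replace = TRUE), cols, drop = FALSE
      ]
      paternal[, cols] <- panel$haplotypes[
        sample.int(n_hap, n, replace = TRUE), cols, drop = FALSE
      ]
    }
    sexes <- switch(sex,
      alternating = rep_len(c("M", "F"), n),
      random = sample(c("M", "F"), n, replace = TRUE)
    )
    ped <- tibble::tibble(
      id = seq_len(n), sex = sexes,
      sire = NA_integer_, dam = NA_integer_, generation = 1L
    )
    new_population(ped, maternal, paternal, panel$sites, panel$map)
  })
}

#' Sample crossover counts and positions for simulated meioses
#'
#' Draws from the crossover model used by gene-dropping: per chromosome and
#' gamete the crossover count is Poisson(genetic length in Morgans) - i.e. 1%
#' crossover probability per cM, no interference - and crossover positions
#' are uniform along the chromosome.
#'
#' @param map A [genetic_map()].
#' @param n Number of gametes.
#' @param seed Integer seed (or NULL).
#' @return A tibble with one row per gamete x chromosome: `gamete`, `chrom`,
#'   `n_crossovers`, and `positions` (list column, cM).
#' @examples
#' mean(sim_crossovers(genetic_map(1, 100, 1e8), 1000, seed = 1)$n_crossovers)
#' @export
sim_crossovers <- function(map, n, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  n <- check_count(n, "n")
  check_seed(seed)
  with_seed_maybe(seed, {
    purrr::pmap(list(map$chrom, map$length_cM), function(ch, len) {
      k <- rpois(n, len / 100)
      tibble::tibble(
        gamete = seq_len(n), chrom = ch, n_crossovers = k,
        positions = purrr::map(k, function(ki) sort(runif(ki, 0, len)))
      )
    }) |> purrr::list_rbind()
  })
}

# Recombinant gametes from parents within a population. `parent_rows` gives,
# per gamete, the row index of the parent individual. Crossover counts are
# Poisson(length in Morgans) per chromosome, positions uniform, and the
# starting haplotype a fair coin.
drop_gametes <- function(pop, parent_rows, recomb_scale = 1) {
  n_gam <- length(parent_rows)
  out <- matrix(0L, n_gam, ncol(pop$maternal))
  chrom_of <- pop$sites$chrom
  for (i in seq_len(nrow(pop$map))) {
    ch <- pop$map$chrom[i]
    len <- pop$map$length_cM[i]
    cols <- which(chrom_of == ch)
    pos <- pop$sites$pos_cM[cols]
    k <- rpois(n_gam, len / 100 * recomb_scale)
    start <- sample.int(2L, n_gam, replace = TRUE) - 1L
    plain <- k == 0L
    if (any(plain)) {
      from_m <- plain & start == 0L
      from_p <- plain & start == 1L
      if (any(from_m)) {
        out[from_m, cols] <- pop$maternal[parent_rows[from_m], cols, drop = FALSE]
      }
      if (any(from_p)) {
        out[from_p, cols] <- pop$paternal[parent_rows[from_p], cols, drop = FALSE]
      }
    }
    for (g in which(!plain)) {
      bks <- sort(runif(k[g], 0, len))
      sel <- (findInterval(pos, bks) + start[g]) %% 2L
      row <- pop$maternal[parent_rows[g], cols]
      swap <- sel == 1L
      row[swap] <- pop$paternal[parent_rows[g], cols][swap]
      out[g, cols] <- row
    }
  }
  out
}

#' Drop one gamete from a parent
#'
#' Simulates meiosis for a single individual: per chromosome the crossover
#' count is Poisson(genetic length in Morgans), i.e. 1% crossover probability
#' per cM, crossover positions are uniform along the chromosome, and the
#' starting parental haplotype is a fair coin.
#'
#' @param pop A `gs_population`.
#' @param id Individual id within `pop`.
#' @param seed Integer seed (or NULL to consume the current RNG stream).
#' @return Integer vector of allele codes over the population's sites.
#' @export
drop_gamete <- function(pop, id, seed = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  row <- match(id, pop$pedigree$id)
  if (is.na(row)) abort(sprintf("No individual with id %s.", id))
  check_seed(seed)
  with_seed_maybe(seed, drop_gametes(pop, row)[1L, ])
}

#' Produce the second generation by gene-dropping
#'
#' Selects sires and dams from the first generation (a uniform random subset
#' of each sex), mates them according to `design`, and builds each progeny
#' from one recombinant gamete per parent via [drop_gamete()]'s crossover
#' model. Dams are partitioned into consecutive groups of `dams_per_sire` per
#' sire.
#'
#' @param gen1 The founder `gs_population`.
#' @param design A [mating_design()].
#' @param seed Integer seed (or NULL).
#' @return A `gs_population` holding only the progeny; `sire`/`dam` columns
#'   reference generation-1 ids and `generation` is 2. Progeny ids continue
#'   after the largest generation-1 id.
#' @export
make_generation2 <- function(gen1, design, seed = NULL) {
  stopifnot(inherits(gen1, "gs_population"), inherits(design, "mating_design"))
  check_seed(seed)
  males <- which(gen1$pedigree$sex == "M")
  females <- which(gen1$pedigree$sex == "F")
  if (length(males) < design$n_sires || length(females) < design$n_dams) {
    abort(sprintf(
      paste0(
        "Insufficient parents: need %d sire(s) and %d dam(s) but generation 1 ",
        "has %d male(s) and %d female(s)."
      ),
      design$n_sires, design$n_dams, length(males), length(females)
    ))
  }

  with_seed_maybe(seed, {
    sire_rows <- sample(males, design$n_sires)
    dam_rows <- sample(females, design$n_dams)
    mating_sire <- rep(sire_rows, each = design$dams_per_sire)
    alloc <- design$allocation
    prog_sire_row <- rep(mating_sire, times = alloc)
    prog_dam_row <- rep(dam_rows, times = alloc)

    paternal <- drop_gametes(gen1, prog_sire_row)
    maternal <- drop_gametes(gen1, prog_dam_row)

    id0 <- max(gen1$pedigree$id)
    ped <- tibble::tibble(
      id = id0 + seq_len(design$n_progeny),
      sex = rep_len(c("M", "F"), design$n_progeny),
      sire = gen1$pedigree$id[prog_sire_row],
      dam = gen1$pedigree$id[prog_dam_row],
      generation = 2L
    )
    new_population(ped, maternal, paternal, gen1$sites, gen1$map)
  })
}

# Row-subset of a population, preserving pedigree order as given.
slice_population <- function(pop, rows) {
  new_population(
    pop$pedigree[rows, , drop = FALSE],
    pop$maternal[rows, , drop = FALSE],
    pop$paternal[rows, , drop = FALSE],
    pop$sites, pop$map
  )
}

#' Sample the prediction set with equal family representation
#'
#' Draws `n` progeny from the second generation such that every dam
#' contributes the same number of progeny (the study used 500 candidates, one
#' per dam). If `n` is not divisible by the number of dams the call fails
#' unless `allow_remainder = TRUE`, in which case the allocation is made as
#' equal as possible (randomly chosen dams contribute one extra).
#'
#' @param gen2 A progeny `gs_population` from [make_generation2()].
#' @param n Number of individuals to draw.
#' @param seed Integer seed (or NULL).
#' @param allow_remainder Permit an as-equal-as-possible allocation when `n`
#'   is not a multiple of the dam count.
#' @return A `gs_population` with `n` individuals.
#' @export
sample_prediction_set <- function(gen2, n, seed = NULL, allow_remainder = FALSE) {
  stopifnot(inherits(gen2, "gs_population"))
  n <- check_count(n, "n")
  check_seed(seed)
  if (n == nrow(gen2$pedigree)) {
    return(gen2)
  }
  if (n > nrow(gen2$pedigree)) {
    abort(sprintf(
      "Requested %d individuals but the generation has only %d.",
      n, nrow(gen2$pedigree)
    ))
  }
  dams <- unique(gen2$pedigree$dam)
  n_dams <- length(dams)
  per_dam <- rep(n %/% n_dams, n_dams)
  if (n %% n_dams != 0L) {
    if (!allow_remainder) {
      abort(sprintf(
        paste0(
          "%d individuals cannot be split equally over %d dam(s); set ",
          "`allow_remainder = TRUE` for an as-equal-as-possible allocation."
        ),
        n, n_dams
      ))
    }
  }
  with_seed_maybe(seed, {
    if (n %% n_dams != 0L) {
      extra <- sample.int(n_dams, n %% n_dams)
      per_dam[extra] <- per_dam[extra] + 1L
    }
    rows <- unlist(purrr::map2(dams, per_dam, function(d, k) {
      if (k == 0L) {
        return(integer())
      }
      avail <- which(gen2$pedigree$dam == d)
      if (length(avail) < k) {
        abort(sprintf(
          "Dam %s has only %d progeny; %d needed for an equal allocation.",
          d, length(avail), k
        ))
      }
      sample(avail, k)
    }), use.names = FALSE)
    slice_population(gen2, sort(rows))
  })
}

#' Genotype dosages of a population
#'
#' True allele-1 dosages (maternal + paternal allele) at the requested sites.
#'
#' @param pop A `gs_population`.
#' @param sites Integer site indices (default: all sites).
#' @return Integer matrix, individuals x sites, with individual ids as row
#'   names.
#' @export
dosage <- function(pop, sites = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  sites <- sites %||% pop$sites$site
  d <- pop$maternal[, sites, drop = FALSE] + pop$paternal[, sites, drop = FALSE]
  rownames(d) <- pop$pedigree$id
  d
}

#' Export a pedigree as a tidy table
#'
#' @param ... One or more `gs_population` objects (e.g. generation 1 and 2).
#' @return A tibble with columns `id`, `sire`, `dam`, `sex`, `generation`.
#' @export
pedigree_table <- function(...) {
  pops <- list(...)
  purrr::list_rbind(purrr::map(pops, function(p) {
    stopifnot(inherits(p, "gs_population"))
    p$pedigree[, c("id", "sire", "dam", "sex", "generation")]
  }))
}
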