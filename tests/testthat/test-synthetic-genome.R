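test_that("simulated panels have the requested dimensions, all segregating", {
  p <- fixture_panel()
  expect_equal(panel_dim(p), c(200L, 600L))
  expect_true(all(p$sites$base_freq > 0 & p$sites$base_freq < 1))
  expect_equal(as.vector(table(p$sites$chrom)), c(300L, 300L))
  # positions strictly increasing within chromosomes
  for (ch in 1:2) {
    expect_false(is.unsorted(p$sites$pos_cM[p$sites$chrom == ch],
      strictly = TRUE
    ))
  }
  # base_freqs recomputable from the haplotypes exactly
  expect_equal(p$sites$base_freq, colMeans(p$haplotypes))
})

test_that("panel simulation is deterministic per seed and rejects bad input", {
  m <- genetic_map(1, 10, 1e7)
  a <- sim_haplotype_panel(20, m, sites_per_chrom = 50, seed = 5,
                           max_generations = 10)
  b <- sim_haplotype_panel(20, m, sites_per_chrom = 50, seed = 5,
                           max_generations = 10)
  expect_identical(a, b)
  c <- sim_haplotype_panel(20, m, sites_per_chrom = 50, seed = 6,
                           max_generations = 10)
  expect_false(identical(a$haplotypes, c$haplotypes))

  expect_error(sim_haplotype_panel(2, m, sites_per_chrom = 10), ">= 4")
  expect_error(sim_haplotype_panel(21, m, sites_per_chrom = 10), "even")
})

test_that("equilibrium spectrum is 1/i-shaped (chi-square against neutral SFS)", {
  # With no forward generations the panel is an exact draw from the neutral
  # equilibrium spectrum; compare binned derived-allele counts against the
  # 1/i expectation with a classical goodness-of-fit test.
  n_hap <- 100
  p <- sim_haplotype_panel(
    n_hap, genetic_map(1, 50, 5e7), sites_per_chrom = 10000,
    seed = 99, max_generations = 0, min_diploids = n_hap / 2
  )
  counts <- round(p$sites$base_freq * n_hap)
  bins <- c(1, 2, 3, 4, 5, 10, 20, n_hap - 1)
  obs <- graphics::hist(counts, breaks = c(0, bins), plot = FALSE)$counts
  i <- seq_len(n_hap - 1)
  pr <- 1 / i / sum(1 / i)
  cuts <- findInterval(i, c(0, bins), left.open = TRUE)
  exp_p <- tapply(pr, cuts, sum)
  chi <- suppressWarnings(stats::chisq.test(obs, p = as.numeric(exp_p)))
  expect_gt(chi$p.value, 1e-4)
  # per-count class sizes decrease: singletons > doubletons > ... > quintons
  low <- vapply(1:5, function(k) sum(counts == k), numeric(1))
  expect_true(all(diff(low) < 0))
})

test_that("drifted panels stay skewed toward rare variants", {
  p <- fixture_panel()
  counts <- round(p$sites$base_freq * 200)
  counts <- pmin(counts, 200 - counts) # fold to minor-allele counts
  # rare sites dominate common ones after the forward phase
  expect_gt(mean(counts <= 10), mean(counts > 50))
  expect_gt(sum(counts <= 5), sum(counts > 5) / 2)
})

test_that("LD decays with genetic distance (sign test, adjacent vs > 50 cM)", {
  p <- fixture_ld_panel()
  h <- p$haplotypes
  pos <- p$sites$pos_cM
  set.seed(31)
  # anchor pairs near the chromosome ends so a > 50 cM partner always exists
  eligible <- which(pos < 40 | pos > 60)
  idx <- sample(eligible[eligible < ncol(h)], 1000, replace = TRUE)
  r2 <- function(i, j) suppressWarnings(cor(h[, i], h[, j]))^2
  adj <- vapply(idx, function(i) r2(i, i + 1L), numeric(1))
  far_j <- vapply(seq_along(idx), function(k) {
    cand <- which(abs(pos - pos[idx[k]]) > 50)
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  far <- vapply(seq_along(idx), function(k) r2(idx[k], far_j[k]), numeric(1))
  ok <- !is.na(adj) & !is.na(far)
  wins <- sum(adj[ok] > far[ok])
  n <- sum(ok)
  # one-sided sign test at the 1e-6 level
  expect_gt(wins, qbinom(1 - 1e-6, n, 0.5))
  expect_gt(mean(adj[ok]), mean(far[ok]))
})

test_that("ms import parses haplotype blocks and maps positions", {
  lines <- c(
    "ms 4 1 -t 5", "1 2 3", "", "//", "segsites: 2",
    "positions: 0.2 0.8", "01", "01", "00", "11"
  )
  p <- read_ms_panel(lines, genetic_map(1, 100, 1e8))
  expect_equal(panel_dim(p), c(4L, 2L))
  # direct allele counts: site 1 carries one derived allele, site 2 three
  expect_equal(p$sites$base_freq, c(1 / 4, 3 / 4))
  expect_equal(p$sites$pos_cM, c(20, 80))
  expect_equal(p$sites$pos_bp, c(2e7, 8e7))
})

test_that("ms import drops monomorphic columns with a warning", {
  lines <- c(
    "//", "segsites: 3", "positions: 0.1 0.5 0.9",
    "010", "011", "000", "010"
  )
  expect_warning(
    p <- read_ms_panel(lines, genetic_map(1, 100, 1e8)),
    "1 monomorphic"
  )
  expect_equal(ncol(p$haplotypes), 2L)
})

test_that("ms import fails on ragged, non-binary, or mismatched input", {
  base <- c("//", "segsites: 2", "positions: 0.1 0.5")
  expect_error(
    read_ms_panel(c(base, "01", "011", "00", "01"), genetic_map(1, 100, 1e8)),
    "length"
  )
  expect_error(
    read_ms_panel(c(base, "01", "0x", "00", "11"), genetic_map(1, 100, 1e8)),
    "other than 0/1"
  )
  expect_error(
    read_ms_panel(
      c("//", "segsites: 3", "positions: 0.1 0.5", "010", "101"),
      genetic_map(1, 100, 1e8)
    ),
    "does not match"
  )
  expect_error(read_ms_panel(c("just", "noise"), genetic_map(1, 100, 1e8)))
})

test_that("panel text checkpoints round-trip losslessly", {
  p <- toy_panel()
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_panel(p, prefix)
  q <- read_panel(prefix)
  expect_equal(q$haplotypes, p$haplotypes, ignore_attr = TRUE)
  expect_equal(q$sites$base_freq, p$sites$base_freq)
  expect_equal(q$map$length_cM, p$map$length_cM)
})

test_that("sample_sites draws equal per-chromosome samples disjoint from exclusions", {
  p <- fixture_panel()
  qtl <- sample_sites(p, 50, seed = 1)
  expect_length(qtl, 100)
  expect_equal(as.vector(table(p$sites$chrom[qtl])), c(50L, 50L))

  mk <- sample_sites(p, 100, exclude = qtl, seed = 2)
  expect_length(intersect(qtl, mk), 0)
  expect_identical(mk, sample_sites(p, 100, exclude = qtl, seed = 2))

  chr1 <- p$sites$site[p$sites$chrom == 1]
  expect_error(sample_sites(p, 10, exclude = chr1, seed = 3), "Chromosome 1")
  expect_error(sample_sites(p, 301, seed = 3), "only")
})
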