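test_that("mating_design allocates progeny as evenly as divisibility allows", {
  d <- mating_design(2, 2, 9)
  expect_equal(d$n_dams, 4)
  expect_equal(d$allocation, c(3L, 2L, 2L, 2L))
  expect_equal(sum(d$allocation), 9)
  expect_equal(mating_design(2, 2, 8)$allocation, rep(2L, 4))
})

test_that("founder chromosomes are verbatim copies of panel haplotypes", {
  p <- toy_panel()
  g <- make_generation1(p, 25, seed = 1)
  for (ch in 1:2) {
    cols <- which(p$sites$chrom == ch)
    pool <- apply(p$haplotypes[, cols, drop = FALSE], 1, paste, collapse = "")
    for (mat in list(g$maternal, g$paternal)) {
      got <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      expect_true(all(got %in% pool))
    }
  }

  # a pool that is all-reference at one site can only produce 0 dosages there
  expect_true(all(dosage(g) >= 0 & dosage(g) <= 2))

  g1 <- make_generation1(fixture_panel(), 50, seed = 2)
  expect_equal(g1$pedigree$sex, rep_len(c("M", "F"), 50))
  expect_true(all(is.na(g1$pedigree$sire)))
  expect_identical(g1, make_generation1(fixture_panel(), 50, seed = 2))
  # random sexes on request
  gr <- make_generation1(fixture_panel(), 50, seed = 2, sex = "random")
  expect_true(all(gr$pedigree$sex %in% c("M", "F")))
})

test_that("founder dosage means track twice the base frequency", {
  p <- fixture_panel()
  g <- make_generation1(p, 1000, seed = 3)
  m <- colMeans(dosage(g))
  exp_m <- 2 * p$sites$base_freq
  se <- sqrt(2 * p$sites$base_freq * (1 - p$sites$base_freq) / 1000)
  within4 <- abs(m - exp_m) <= 4 * se
  expect_gt(mean(within4), 0.995)
})

test_that("gamete dropping respects the map and parental genomes", {
  p <- toy_panel()
  g1 <- make_generation1(p, 4, seed = 1)
  gam <- drop_gamete(g1, 1, seed = 9)
  expect_length(gam, 6)
  # every allele matches one of the parent's two haplotypes
  expect_true(all(gam == g1$maternal[1, ] | gam == g1$paternal[1, ]))

  # homozygous parent: gamete identical regardless of crossovers
  g1$paternal <- g1$maternal
  expect_equal(drop_gamete(g1, 2, seed = 10), unname(g1$maternal[2, ]))
})

test_that("zero-length chromosomes never recombine", {
  xo <- sim_crossovers(genetic_map(1, 0, 1e6), 500, seed = 3)
  expect_true(all(xo$n_crossovers == 0L))
})

test_that("crossover counts are Poisson with mean length-in-Morgans", {
  xo <- sim_crossovers(genetic_map(1, 100, 1e8), 20000, seed = 4)
  expect_equal(mean(xo$n_crossovers), 1, tolerance = 0.03)
  # chi-square against Poisson(1) on counts 0..4+
  obs <- table(factor(pmin(xo$n_crossovers, 4), levels = 0:4))
  pr <- c(dpois(0:3, 1), 1 - ppois(3, 1))
  chi <- stats::chisq.test(as.vector(obs), p = pr)
  expect_gt(chi$p.value, 1e-4)
  # positions uniform within (0, length)
  pos <- unlist(xo$positions)
  expect_true(all(pos >= 0 & pos <= 100))
  expect_gt(stats::ks.test(pos, "punif", 0, 100)$p.value, 1e-4)
})

test_that("generation 2 bookkeeping and Mendelian consistency hold", {
  p <- fixture_panel()
  g1 <- make_generation1(p, 30, seed = 5)
  g2 <- make_generation2(g1, mating_design(2, 2, 8), seed = 6)
  expect_equal(nrow(g2$pedigree), 8)
  expect_true(all(!is.na(g2$pedigree$sire)) && all(!is.na(g2$pedigree$dam)))
  expect_equal(as.vector(table(g2$pedigree$dam)), rep(2L, 4))
  # parents precede progeny (acyclic two-generation pedigree)
  expect_true(all(g2$pedigree$id > max(g1$pedigree$id)))
  expect_true(all(c(g2$pedigree$sire, g2$pedigree$dam) %in% g1$pedigree$id))
  expect_true(mendelian_ok(g1, g2))

  expect_error(
    make_generation2(g1, mating_design(20, 20, 10), seed = 1),
    "Insufficient parents"
  )
})

test_that("full sibs share more of their genome than half sibs", {
  p <- fixture_panel()
  g1 <- make_generation1(p, 30, seed = 7)
  g2 <- make_generation2(g1, mating_design(2, 3, 60), seed = 8)
  d <- dosage(g2)
  ped <- g2$pedigree
  ibs <- function(i, j) mean(2 - abs(d[i, ] - d[j, ]))
  pairs <- utils::combn(nrow(ped), 2)
  rel <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    same_sire <- ped$sire[i] == ped$sire[j]
    same_dam <- ped$dam[i] == ped$dam[j]
    if (same_sire && same_dam) "full" else if (same_sire || same_dam) "half" else "un"
  })
  sim <- apply(pairs, 2, function(ij) ibs(ij[1], ij[2]))
  expect_gt(mean(sim[rel == "full"]), mean(sim[rel == "half"]))
  expect_gt(mean(sim[rel == "half"]), mean(sim[rel == "un"]))
})

test_that("prediction sets represent every dam equally", {
  p <- fixture_panel()
  g1 <- make_generation1(p, 30, seed = 9)
  g2 <- make_generation2(g1, mating_design(2, 3, 30), seed = 10) # 6 dams x 5
  ps <- sample_prediction_set(g2, 6, seed = 11)
  expect_equal(as.vector(table(ps$pedigree$dam)), rep(1L, 6))
  ps2 <- sample_prediction_set(g2, 12, seed = 11)
  expect_equal(as.vector(table(ps2$pedigree$dam)), rep(2L, 6))
  expect_identical(ps$pedigree, sample_prediction_set(g2, 6, seed = 11)$pedigree)

  # whole generation: returned as is
  expect_identical(sample_prediction_set(g2, 30, seed = 1), g2)
  # indivisible without opt-in
  expect_error(sample_prediction_set(g2, 7, seed = 1), "allow_remainder")
  ps3 <- sample_prediction_set(g2, 7, seed = 1, allow_remainder = TRUE)
  expect_equal(nrow(ps3$pedigree), 7)
  expect_true(all(table(ps3$pedigree$dam) %in% 1:2))
  expect_error(sample_prediction_set(g2, 31, seed = 1), "only")
})

test_that("pedigree_table binds generations into tidy records", {
  p <- toy_panel()
  g1 <- make_generation1(p, 6, seed = 1)
  g2 <- make_generation2(g1, mating_design(1, 2, 4), seed = 2)
  tab <- pedigree_table(g1, g2)
  expect_equal(nrow(tab), 10)
  expect_named(tab, c("id", "sire", "dam", "sex", "generation"))
  expect_equal(sum(tab$generation == 2), 4)
})
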