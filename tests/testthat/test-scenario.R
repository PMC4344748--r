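test_that("budget depth spreads total coverage exactly", {
  expect_identical(budget_depth(10000, 500), 20)
  expect_identical(budget_depth(1000, 50000), 0.02)
  expect_identical(budget_depth(5000, 1), 5000)
  expect_error(budget_depth(0, 10), "> 0")
  expect_error(budget_depth(100, 0), ">= 1")
})

test_that("scenario specs validate their design-specific inputs", {
  expect_error(scenario_spec("A1", markers = 100), "x_train")
  expect_error(
    scenario_spec("A1", markers = 100, x_train = list(-1)),
    "positive depths"
  )
  expect_error(scenario_spec("A3", markers = 100, n_train = c(10, 20)), "total_x")
  expect_error(
    scenario_spec("A4", markers = 100, total_x = 10, n_predict = 10,
                  n_selected = 50),
    "exceed"
  )
  s <- scenario_spec("A1", markers = c(100, 200), x_train = list(1, "array"),
                     n_train = 50, n_predict = 10)
  expect_s3_class(s, "scenario_spec")
})

test_that("A2 grids enumerate every depth combination with echoed metadata", {
  s <- scenario_spec("A2", markers = 100, x_train = list(0.1, 1),
                     n_train = 50, n_predict = 10, replicates = 1)
  cells <- gbselect:::scenario_cells(s)
  expect_equal(nrow(cells), 4)
  expect_setequal(
    paste(cells$x_train, cells$x_predict),
    c("0.1 0.1", "0.1 1", "1 0.1", "1 1")
  )
  expect_true(all(cells$n_train == 50 & cells$n_predict == 10))
})

test_that("A3/A4 cells conserve the coverage budget exactly", {
  s3 <- scenario_spec("A3", markers = 100, total_x = 1000,
                      n_train = c(500, 1000, 5000), n_predict = 10)
  c3 <- gbselect:::scenario_cells(s3)
  expect_true(all(c3$x_train * c3$n_train == 1000))
  expect_setequal(unique(c3$x_train), c(2, 1, 0.2))

  s4 <- scenario_spec("A4", markers = 100, total_x = 10000,
                      n_predict = c(500, 50000), n_train = 1000,
                      n_selected = 25)
  c4 <- gbselect:::scenario_cells(s4)
  expect_true(all(c4$x_predict * c4$n_predict == 10000))
  # both training variants present for every prediction-set size
  expect_equal(
    as.vector(table(c4$platform_train)),
    c(2L, 2L)
  )
  # the GBS-trained variant matches training size and depth to prediction
  gbs <- c4[c4$platform_train == "gbs", ]
  expect_equal(gbs$n_train, gbs$n_predict)
  expect_equal(gbs$x_train, gbs$x_predict)
})

test_that("the full-scale study grid is expressible", {
  cfg <- study_config()
  expect_equal(nrow(cfg$map), 30)
  expect_equal(cfg$map$length_cM[1], 100)
  expect_equal(cfg$map$length_bp[1], 1e8)
  expect_equal(cfg$qtl_per_chrom * 30, 9000)
  expect_equal(cfg$n_sires * cfg$dams_per_sire, 500)
  s <- scenario_spec("A3", markers = 3e5, total_x = 10000,
                     n_train = c(500, 1000, 5000, 10000, 20000, 50000),
                     n_predict = 500)
  cells <- gbselect:::scenario_cells(s)
  expect_true(all(cells$x_train * cells$n_train == 10000))
})

test_that("infeasible scenarios fail before any computation", {
  cfg <- tiny_config() # 2 sires x 3 dams -> needs >= 12 founders
  s <- scenario_spec("A1", markers = 20, x_train = list(1),
                     n_train = 8, n_predict = 6, replicates = 1)
  expect_error(run_scenario(s, cfg), "cannot supply")

  s2 <- scenario_spec("A1", markers = 20, x_train = list(1),
                      n_train = 40, n_predict = 60, replicates = 1)
  expect_error(run_scenario(s2, cfg), "exceeds the generation-2")

  s3 <- scenario_spec("A1", markers = 25, x_train = list(1),
                      n_train = 40, n_predict = 6, replicates = 1)
  expect_error(run_scenario(s3, cfg), "multiples")
})

test_that("run_scenario produces deterministic per-replicate records", {
  cfg <- tiny_config()
  s <- scenario_spec("A1", markers = 40, x_train = list(0.5, "array"),
                     n_train = 40, n_predict = 6, replicates = 2, seed = 99)
  r <- run_scenario(s, cfg)
  expect_s3_class(r, "gs_scenarios")
  expect_equal(nrow(r), 4) # 2 cells x 2 replicates
  expect_true(all(abs(r$accuracy) <= 1))
  expect_true(all(is.finite(r$bias)))

  # array cells bypass the GBS path entirely
  arr <- r[r$platform_train == "array", ]
  expect_true(all(arr$fill_train == 0))
  expect_true(all(is.infinite(arr$realized_x_train)))

  # byte-identical rerun from the same master seed
  expect_identical(r, run_scenario(s, cfg))
  # cache off gives the same results
  expect_identical(r, run_scenario(s, cfg, cache = FALSE))
})

test_that("A4 records compute response via the breeders' equation", {
  cfg <- tiny_config()
  s <- scenario_spec("A4", markers = 40, total_x = 24,
                     n_predict = c(12, 24), n_train = 40, n_selected = 2,
                     replicates = 1, seed = 7)
  r <- run_scenario(s, cfg)
  expect_equal(nrow(r), 4) # 2 sizes x 2 training variants
  expect_equal(r$response, r$intensity * r$accuracy)
  expect_equal(
    sort(unique(r$intensity)),
    sort(selection_intensity(c(2 / 24, 2 / 12)))
  )
})

test_that("aggregation means over replicates (hand-checked)", {
  rec <- tibble::tibble(
    design = "A1", markers = 10L, n_train = 5L, n_predict = 3L,
    platform_train = "gbs", x_train = 1, platform_predict = "gbs",
    x_predict = 1, total_x = NA_real_, n_selected = NA_integer_,
    replicate = 1:3,
    accuracy = c(0.2, 0.4, 0.9), bias = c(1, 2, 3),
    intensity = NA_real_, response = c(NA_real_, NA_real_, NA_real_)
  )
  agg <- aggregate_scenarios(rec)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$accuracy, 0.5)
  expect_equal(agg$bias, 2)
  expect_equal(agg$accuracy_sd, sd(c(0.2, 0.4, 0.9)))
  expect_equal(agg$n_replicates, 3)

  # ten identical records: zero dispersion
  rec10 <- rec[rep(1, 10), ]
  rec10$replicate <- 1:10
  agg10 <- aggregate_scenarios(rec10)
  expect_equal(agg10$accuracy_sd, 0)
  expect_equal(agg10$accuracy, 0.2)

  # single replicate: mean equals the record
  agg1 <- aggregate_scenarios(rec[1, ])
  expect_equal(agg1$accuracy, 0.2)
  expect_error(aggregate_scenarios(rec[, 1:3]), "run_scenario")
})

test_that("scenario results export as tidy text", {
  rec <- tibble::tibble(
    design = "A1", markers = 10L, replicate = 1:2,
    accuracy = c(0.1, 0.2), bias = c(1, 1.1)
  )
  path <- file.path(withr::local_tempdir(), "records.tsv")
  write_scenarios(rec, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$accuracy, rec$accuracy)
})
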