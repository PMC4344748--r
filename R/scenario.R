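#' Per-individual depth under a fixed total sequencing budget
#'
#' Spreading a fixed total coverage budget (e.g. 1000x, 5000x, or 10 000x per
#' genotyped locus) across `n_individuals` gives each individual exactly
#' `total_x / n_individuals` mean read depth, conserving the budget.
#'
#' @param total_x Total available coverage (> 0).
#' @param n_individuals Number of genotyped individuals (>= 1).
#' @return The per-individual mean depth.
#' @examples
#' budget_depth(10000, 500) # 20x
#' budget_depth(1000, 50000) # 0.02x
#' @export
budget_depth <- function(total_x, n_individuals) {
  check_number(total_x, "total_x", min = 0, strict = TRUE)
  n_individuals <- check_count(n_individuals, "n_individuals")
  total_x / n_individuals
}

#' Simulation configuration for a scenario run
#'
#' Bundles the genome, base-population, pedigree, and trait parameters shared
#' by every cell of a scenario grid. [desk_config()] is the scaled-down
#' preset used throughout the package's tests and examples; [study_config()]
#' encodes the full-scale study conditions (30 chromosomes of 100 cM / 1e8
#' bp, 1000 base haplotypes, 9000 QTL, 25 sires x 20 dams), which are
#' expressible here but sized for cluster rather than desk hardware.
#'
#' @param n_chromosomes,chr_length_cM,chr_length_bp Genome layout.
#' @param sites_per_chrom Segregating sites per chromosome in the base panel.
#' @param n_haplotypes Base haplotypes in the panel.
#' @param ne Effective-size history ([ne_schedule()]).
#' @param scale,max_generations,oversample Forward-simulation controls passed
#'   to [sim_haplotype_panel()].
#' @param qtl_per_chrom QTL per chromosome.
#' @param h2 Trait heritability.
#' @param n_sires,dams_per_sire Mating design of generation 2.
#' @param exclude_qtl_from_markers Keep marker and QTL samples disjoint
#'   (default TRUE).
#' @return An object of class `gs_sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5, chr_length_cM = 20,
                       chr_length_bp = 2e7, sites_per_chrom = 2000,
                       n_haplotypes = 400, ne = ne_schedule(),
                       scale = 1, max_generations = 100, oversample = 1.4,
                       qtl_per_chrom = 60, h2 = 0.25,
                       n_sires = 5, dams_per_sire = 10,
                       exclude_qtl_from_markers = TRUE) {
  cfg <- list(
    map = genetic_map(n_chromosomes, chr_length_cM, chr_length_bp),
    sites_per_chrom = check_count(sites_per_chrom, "sites_per_chrom"),
    n_haplotypes = check_count(n_haplotypes, "n_haplotypes", min = 4L),
    ne = ne, scale = scale,
    max_generations = check_count(max_generations, "max_generations", min = 0L),
    oversample = oversample,
    qtl_per_chrom = check_count(qtl_per_chrom, "qtl_per_chrom"),
    h2 = check_number(h2, "h2", min = 0, strict = TRUE),
    n_sires = check_count(n_sires, "n_sires"),
    dams_per_sire = check_count(dams_per_sire, "dams_per_sire"),
    exclude_qtl_from_markers = isTRUE(exclude_qtl_from_markers)
  )
  structure(cfg, class = "gs_sim_config")
}

#' @rdname sim_config
#' @export
desk_config <- function() sim_config()

#' @rdname sim_config
#' @export
study_config <- function() {
  sim_config(
    n_chromosomes = 30, chr_length_cM = 100, chr_length_bp = 1e8,
    sites_per_chrom = 56000, n_haplotypes = 1000,
    scale = 1, max_generations = 1000,
    qtl_per_chrom = 300, n_sires = 25, dams_per_sire = 20
  )
}

#' @export
print.gs_sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<gs_sim_config> %d chromosome(s) x %g cM / %.3g bp; %d sites/chrom; ",
      "%d base haplotypes\n  %d QTL/chrom; h2 = %g; %d sires x %d dams/sire\n"
    ),
    nrow(x$map), x$map$length_cM[1], x$map$length_bp[1], x$sites_per_chrom,
    x$n_haplotypes, x$qtl_per_chrom, x$h2, x$n_sires, x$dams_per_sire
  ))
  invisible(x)
}

#' Specify one analysis design of the simulation study
#'
#' The four designs compare GBS and SNP-array genotyping:
#' * **A1** - the same read depth `x` in training and prediction sets (grid
#'   over `x_train`, which may include the `"array"` sentinel);
#' * **A2** - all combinations of `x_train` and `x_predict`;
#' * **A3** - a fixed total coverage `total_x` spread over an expanding
#'   training set (`n_train` grid; per-individual depth is
#'   [budget_depth()]), with the prediction set genotyped on arrays and/or
#'   with GBS at the training depth;
#' * **A4** - the same budget spread over an expanding prediction set
#'   (`n_predict` grid) with `n_selected` males selected; accuracies come
#'   either from an array-trained model (`n_train` individuals) or from a
#'   GBS-trained model matching the prediction set, and the breeders'
#'   equation converts them to response to selection.
#'
#' Depth values must be positive numbers or the string `"array"`; the two
#' never mix within one cell's role. Budget conservation is exact:
#' per-individual depth times the set size equals `total_x` in every A3/A4
#' cell.
#'
#' @param design One of `"A1"`, `"A2"`, `"A3"`, `"A4"`.
#' @param markers Vector of total marker counts (densities) to run.
#' @param x_train Depth levels for training (A1: shared with prediction).
#' @param x_predict Depth levels for prediction (A2); defaults to `x_train`.
#' @param n_train Training-set size(s); scalar except in A3.
#' @param n_predict Prediction-set size(s); scalar except in A4.
#' @param total_x Total coverage budget (A3/A4).
#' @param n_selected Number of males selected (A4).
#' @param predict_with Prediction-set platform(s) in A3: subset of
#'   `c("array", "gbs")`.
#' @param replicates Number of simulation replicates.
#' @param seed Master seed; every replicate and cell derives its streams from
#'   it deterministically.
#' @return An object of class `scenario_spec`.
#' @seealso [run_scenario()]
#' @export
scenario_spec <- function(design = c("A1", "A2", "A3", "A4"),
                          markers,
                          x_train = NULL, x_predict = NULL,
                          n_train = NULL, n_predict = 100,
                          total_x = NULL, n_selected = NULL,
                          predict_with = c("array", "gbs"),
                          replicates = 10, seed = 1) {
  design <- match.arg(design)
  markers <- vapply(markers, check_count, integer(1), name = "markers")
  replicates <- check_count(replicates, "replicates")
  check_seed(seed, allow_null = FALSE)
  predict_with <- match.arg(predict_with, c("array", "gbs"), several.ok = TRUE)

  check_depths <- function(x, name) {
    if (is.null(x)) abort(sprintf("`%s` is required for design %s.", name, design))
    ok <- vapply(x, function(v) {
      identical(v, "array") ||
        (is.numeric(v) && length(v) == 1L && !is.na(v) && v > 0)
    }, logical(1))
    if (!all(ok)) {
      abort(sprintf("`%s` entries must be positive depths or \"array\".", name))
    }
    as.list(x)
  }

  spec <- list(
    design = design, markers = markers, replicates = replicates, seed = seed,
    n_predict = NULL, n_train = NULL, x_train = NULL, x_predict = NULL,
    total_x = NULL, n_selected = NULL, predict_with = predict_with
  )
  if (design %in% c("A1", "A2")) {
    spec$x_train <- check_depths(x_train, "x_train")
    spec$x_predict <- if (design == "A2") {
      check_depths(x_predict %||% x_train, "x_predict")
    } else {
      NULL
    }
    spec$n_train <- check_count(n_train %||% 1000, "n_train")
    spec$n_predict <- check_count(n_predict, "n_predict")
  } else if (design == "A3") {
    spec$total_x <- check_number(total_x, "total_x", min = 0, strict = TRUE)
    if (is.null(n_train)) abort("`n_train` (a size grid) is required for A3.")
    spec$n_train <- vapply(n_train, check_count, integer(1), name = "n_train")
    spec$n_predict <- check_count(n_predict, "n_predict")
  } else { # A4
    spec$total_x <- check_number(total_x, "total_x", min = 0, strict = TRUE)
    spec$n_predict_grid <- vapply(n_predict, check_count, integer(1),
      name = "n_predict"
    )
    spec$n_train <- check_count(n_train %||% 1000, "n_train")
    spec$n_selected <- check_count(n_selected %||% 25, "n_selected")
    if (any(spec$n_selected > spec$n_predict_grid)) {
      abort("`n_selected` cannot exceed any prediction-set size.")
    }
  }
  structure(spec, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> design %s; %d marker densit%s; %d replicate(s); seed %d\n",
    x$design, length(x$markers), if (length(x$markers) == 1) "y" else "ies",
    x$replicates, x$seed
  ))
  print(scenario_cells(x))
  invisible(x)
}

# Expand a spec into its grid of cells (one row per scenario cell).
scenario_cells <- function(spec) {
  fmt_x <- function(v) if (identical(v, "array")) NA_real_ else as.numeric(v)
  platform <- function(v) if (identical(v, "array")) "array" else "gbs"

  base <- switch(spec$design,
    A1 = purrr::map(spec$x_train, function(v) {
      tibble::tibble(
        n_train = spec$n_train, n_predict = spec$n_predict,
        platform_train = platform(v), x_train = fmt_x(v),
        platform_predict = platform(v), x_predict = fmt_x(v),
        n_gen1 = spec$n_train, n_gen2 = spec$n_train,
        total_x = NA_real_, n_selected = NA_integer_
      )
    }) |> purrr::list_rbind(),
    A2 = tidyr::expand_grid(xt = spec$x_train, xp = spec$x_predict) |>
      purrr::pmap(function(xt, xp) {
        tibble::tibble(
          n_train = spec$n_train, n_predict = spec$n_predict,
          platform_train = platform(xt), x_train = fmt_x(xt),
          platform_predict = platform(xp), x_predict = fmt_x(xp),
          n_gen1 = spec$n_train, n_gen2 = spec$n_train,
          total_x = NA_real_, n_selected = NA_integer_
        )
      }) |> purrr::list_rbind(),
    A3 = tidyr::expand_grid(n = spec$n_train, pw = spec$predict_with) |>
      purrr::pmap(function(n, pw) {
        x <- budget_depth(spec$total_x, n)
        tibble::tibble(
          n_train = n, n_predict = spec$n_predict,
          platform_train = "gbs", x_train = x,
          platform_predict = pw,
          x_predict = if (pw == "gbs") x else NA_real_,
          n_gen1 = n, n_gen2 = n,
          total_x = spec$total_x, n_selected = NA_integer_
        )
      }) |> purrr::list_rbind(),
    A4 = tidyr::expand_grid(
      n = spec$n_predict_grid, trained = c("array", "gbs")
    ) |>
      purrr::pmap(function(n, trained) {
        x <- budget_depth(spec$total_x, n)
        array_trained <- trained == "array"
        tibble::tibble(
          n_train = if (array_trained) spec$n_train else n,
          n_predict = n,
          platform_train = trained,
          x_train = if (array_trained) NA_real_ else x,
          platform_predict = "gbs", x_predict = x,
          n_gen1 = if (array_trained) spec$n_train else n,
          n_gen2 = n,
          total_x = spec$total_x, n_selected = spec$n_selected
        )
      }) |> purrr::list_rbind()
  )
  dplyr::mutate(base, design = spec$design, .before = 1)
}

#' Run a scenario grid
#'
#' Executes every cell of the design grid over all replicates. Within a
#' replicate the base panel, trait architecture, and marker samples are drawn
#' once and shared by all cells, and each required cohort size gets its own
#' freshly gene-dropped pedigree, so cells are paired within replicates; all
#' random streams derive deterministically from the spec's master seed, so
#' the result table is reproducible and independent of cell evaluation order.
#'
#' Per cell and replicate the pipeline is: genotype the generation-1 training
#' cohort (GBS at its depth, or error-free array), fit the ridge model with
#' the known variance components (sigma_g2 = realized TBV variance of the
#' training cohort, sigma_e2 from the phenotype simulation, sigma_beta2 from
#' [derive_sigma_beta2()]), genotype and predict the generation-2 prediction
#' set, and score accuracy, bias, and - when `n_selected` is set - response
#' to selection.
#'
#' @param spec A [scenario_spec()].
#' @param config A [sim_config()]; default [desk_config()].
#' @param verbose Print per-replicate progress.
#' @param cache Reuse base panels across calls that share the master seed,
#'   replicate index, and configuration (default TRUE); results are
#'   identical either way because panels are deterministic in those inputs.
#' @return A tibble of class `gs_scenarios`, one row per cell x replicate,
#'   with the cell descriptors plus `accuracy`, `bias`, `intensity`,
#'   `response`, `realized_x_train`, `fill_train`, `realized_x_predict`,
#'   `fill_predict`.
#' @export
run_scenario <- function(spec, config = desk_config(), verbose = FALSE,
                         cache = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(config, "gs_sim_config"))
  cells <- scenario_cells(spec)
  n_chrom <- nrow(config$map)
  if (any(cells$n_train < 2L)) abort("Training sets need >= 2 individuals.")
  densities <- spec$markers
  if (any(densities %% n_chrom != 0L)) {
    abort(sprintf(
      "Marker densities must be multiples of the chromosome count (%d).",
      n_chrom
    ))
  }
  cells <- tidyr::expand_grid(markers = densities, cells)
  check_scenario_feasible(cells, config)

  master <- spec$seed
  out <- purrr::map(seq_len(spec$replicates), function(r) {
    if (verbose) message(sprintf("replicate %d/%d", r, spec$replicates))
    world <- replicate_world(config, master, r, densities, cache = cache)
    purrr::pmap(cells, function(...) {
      cell <- list(...)
      res <- eval_cell(cell, world, config, master, r)
      tibble::as_tibble(c(cell, replicate = r, res))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(out) <- c("gs_scenarios", class(out))
  out
}

check_scenario_feasible <- function(cells, config) {
  n_dams <- config$n_sires * config$dams_per_sire
  need_f <- n_dams
  need_m <- config$n_sires
  bad <- cells$n_gen1 < 2 * max(need_f, need_m)
  if (any(bad)) {
    abort(sprintf(
      paste0(
        "Generation-1 size %d cannot supply %d sires and %d dams under ",
        "alternating sexes; enlarge the cohort or shrink the mating design."
      ),
      min(cells$n_gen1[bad]), need_m, need_f
    ))
  }
  if (any(cells$n_predict > cells$n_gen2)) {
    abort("`n_predict` exceeds the generation-2 size in at least one cell.")
  }
}

# Panels are deterministic in (config, master seed, replicate), so runs of
# different designs at the same seed share them; a small package-level cache
# avoids re-simulating.
the_panel_cache <- new.env(parent = emptyenv())

config_key <- function(config) {
  paste(
    nrow(config$map), config$map$length_cM[1], config$map$length_bp[1],
    config$sites_per_chrom, config$n_haplotypes, config$scale,
    config$max_generations, config$oversample,
    paste(config$ne$time_ago, collapse = ","),
    paste(config$ne$ne, collapse = ","),
    config$ne$generation_interval,
    sep = "|"
  )
}

# Everything shared by all cells of one replicate: the panel, the trait
# architecture, the marker samples, and a lazily built cache of pedigrees
# (one per distinct cohort-size pair).
replicate_world <- function(config, master, r, densities, cache = TRUE) {
  key <- paste(config_key(config), master, r, sep = "|")
  panel <- if (cache && !is.null(the_panel_cache[[key]])) {
    the_panel_cache[[key]]
  } else {
    p <- sim_haplotype_panel(
      n_haplotypes = config$n_haplotypes, map = config$map, ne = config$ne,
      sites_per_chrom = config$sites_per_chrom,
      seed = derive_seed(master, r, 1L),
      scale = config$scale, max_generations = config$max_generations,
      oversample = config$oversample
    )
    if (cache) the_panel_cache[[key]] <- p
    p
  }
  qtl_seed <- derive_seed(master, r, 2L)
  arch <- sample_trait_architecture(
    panel, per_chromosome = config$qtl_per_chrom, seed = qtl_seed
  )
  exclude <- if (config$exclude_qtl_from_markers) arch$qtl$site else integer()
  marker_sets <- purrr::map(densities, function(m) {
    sample_sites(
      panel, m / nrow(config$map),
      exclude = exclude, seed = derive_seed(master, r, 3L, m)
    )
  })
  names(marker_sets) <- as.character(densities)

  cache <- new.env(parent = emptyenv())
  get_cohorts <- function(n_gen1, n_gen2) {
    key <- paste(n_gen1, n_gen2, sep = "_")
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    gen1 <- make_generation1(
      panel, n_gen1, seed = derive_seed(master, r, 4L, n_gen1, n_gen2)
    )
    design <- mating_design(config$n_sires, config$dams_per_sire, n_gen2)
    gen2 <- make_generation2(
      gen1, design, seed = derive_seed(master, r, 5L, n_gen1, n_gen2)
    )
    tbv1 <- true_breeding_values(gen1, arch)
    phen <- simulate_phenotypes(
      tbv1, h2 = config$h2, seed = derive_seed(master, r, 6L, n_gen1, n_gen2)
    )
    cache[[key]] <- list(gen1 = gen1, gen2 = gen2, phen = phen)
    cache[[key]]
  }
  list(
    panel = panel, arch = arch, marker_sets = marker_sets,
    get_cohorts = get_cohorts
  )
}

eval_cell <- function(cell, world, config, master, r) {
  sites <- world$marker_sets[[as.character(cell$markers)]]
  freqs <- world$panel$sites$base_freq[sites]
  cohorts <- world$get_cohorts(cell$n_gen1, cell$n_gen2)
  code <- label_code(paste(
    cell$design, cell$markers, cell$n_train, cell$n_predict,
    cell$platform_train, cell$x_train, cell$platform_predict, cell$x_predict
  ))

  train_geno <- if (cell$platform_train == "array") {
    genotype_array(cohorts$gen1, sites)
  } else {
    genotype_gbs(cohorts$gen1, sites, cell$x_train,
      seed = derive_seed(master, r, 7L, code)
    )
  }
  pred_set <- sample_prediction_set(
    cohorts$gen2, cell$n_predict,
    seed = derive_seed(master, r, 8L, cell$n_gen1, cell$n_gen2, cell$n_predict)
  )
  pred_geno <- if (cell$platform_predict == "array") {
    genotype_array(pred_set, sites)
  } else {
    genotype_gbs(pred_set, sites, cell$x_predict,
      seed = derive_seed(master, r, 9L, code)
    )
  }

  phen <- cohorts$phen
  sigma_beta2 <- derive_sigma_beta2(phen$sigma_g2, freqs)
  model <- fit_ridge(train_geno, phen$data$y, phen$sigma_e2, sigma_beta2)
  ebv <- predict_ebv(model, pred_geno)
  tbv <- true_breeding_values(pred_set, world$arch)

  acc <- prediction_accuracy(tbv, ebv)
  bias <- prediction_bias(tbv, ebv)
  if (!is.na(cell$n_selected)) {
    p <- cell$n_selected / cell$n_predict
    intensity <- selection_intensity(p)
    response <- intensity * acc
  } else {
    intensity <- NA_real_
    response <- NA_real_
  }
  list(
    accuracy = acc, bias = bias, intensity = intensity, response = response,
    realized_x_train = train_geno$realized_depth,
    fill_train = fraction_filled(train_geno),
    realized_x_predict = pred_geno$realized_depth,
    fill_predict = fraction_filled(pred_geno)
  )
}

#' Aggregate scenario replicates
#'
#' Means (with sd and replicate count) over replicates for every scenario
#' cell, matching the study's presentation of results as replicate means.
#'
#' @param records A `gs_scenarios` tibble from [run_scenario()].
#' @return A tibble of class `gs_summary`, one row per cell, with
#'   `accuracy`, `bias`, `response` means plus `*_sd` and `n_replicates`.
#' @export
aggregate_scenarios <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("design", "markers", "accuracy", "bias", "replicate")
  if (!all(need %in% names(records))) {
    abort("`records` does not look like a run_scenario() result.")
  }
  keys <- intersect(
    c(
      "design", "markers", "n_train", "n_predict", "platform_train",
      "x_train", "platform_predict", "x_predict", "total_x", "n_selected"
    ),
    names(records)
  )
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(
        dplyr::any_of(c("accuracy", "bias", "response")),
        list(mean = ~ mean(.x), sd = ~ sd(.x)),
        .names = "{.col}_{.fn}"
      ),
      .groups = "drop"
    ) |>
    dplyr::rename(
      accuracy = "accuracy_mean", bias = "bias_mean"
    )
  if ("response_mean" %in% names(out)) {
    out <- dplyr::rename(out, response = "response_mean")
  }
  class(out) <- c("gs_summary", class(out))
  out
}

#' Export scenario results as tidy text
#'
#' @param records A `gs_scenarios` or `gs_summary` tibble.
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
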