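#' Marker-effect variance from the genetic variance
#'
#' The standard SNP-BLUP convention: dividing the (known) additive genetic
#' variance by the sum of marker heterozygosities,
#' `sigma_beta2 = sigma_g2 / sum(2 p_j (1 - p_j))`, so that markers jointly
#' account for the genetic variance.
#'
#' @param sigma_g2 Additive genetic variance (> 0).
#' @param freqs Allele-1 frequencies of the markers, each in (0, 1).
#' @param method `"sum2pq"` (default) or `"per_marker"`
#'   (`sigma_g2 / n_markers`).
#' @return The marker-effect variance (a single number).
#' @examples
#' derive_sigma_beta2(1, 0.5) # one marker at p = 0.5 -> 2
#' @export
derive_sigma_beta2 <- function(sigma_g2, freqs,
                               method = c("sum2pq", "per_marker")) {
  check_number(sigma_g2, "sigma_g2", min = 0, strict = TRUE)
  method <- match.arg(method)
  if (length(freqs) == 0L || anyNA(freqs) ||
      any(freqs <= 0) || any(freqs >= 1)) {
    abort("`freqs` must be non-empty with every value strictly in (0, 1).")
  }
  denom <- switch(method,
    sum2pq = sum(2 * freqs * (1 - freqs)),
    per_marker = length(freqs)
  )
  if (denom <= 0) abort("Degenerate frequency vector: sum of 2pq is zero.")
  sigma_g2 / denom
}

as_dosage_matrix <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) {
    list(x = genotypes$dosages, freqs = genotypes$freqs)
  } else if (is.matrix(genotypes)) {
    list(x = genotypes, freqs = NULL)
  } else {
    abort("`genotypes` must be a `genotype_matrix` or a numeric matrix.")
  }
}

#' Fit the ridge-regression (SNP-BLUP) marker model
#'
#' Fits `y = alpha + Z beta + e` with `beta ~ N(0, sigma_beta2)` and known
#' variance components, i.e. the ridge solution
#' `beta = (Z'Z + lambda I)^{-1} Z'(y - mean(y))` with
#' `lambda = sigma_e2 / sigma_beta2`, where `Z` is the dosage matrix with
#' per-marker centering offsets subtracted. With known variances the
#' posterior mean of the Bayesian ridge model is this deterministic solve, so
#' no sampler is involved. When markers outnumber individuals the
#' mathematically equivalent dual (kernel) solve
#' `beta = Z'(ZZ' + lambda I)^{-1}(y - mean(y))` is used.
#'
#' @param genotypes Training `genotype_matrix` (or plain dosage matrix),
#'   individuals x markers.
#' @param y Numeric phenotype vector, one per training individual.
#' @param sigma_e2 Residual variance (> 0).
#' @param sigma_beta2 Marker-effect variance (> 0), e.g. from
#'   [derive_sigma_beta2()].
#' @param center Per-marker centering offsets. Default: twice the base allele
#'   frequency when `genotypes` carries frequencies, otherwise the column
#'   means.
#' @param method `"auto"` (dual when p > n), `"primal"`, or `"dual"`.
#' @return An object of class `gs_ridge`: list with `alpha` (intercept, the
#'   phenotype mean), `beta` (marker effects), `lambda`, `sigma_e2`,
#'   `sigma_beta2`, `center`, `method`, `n`, `p`.
#' @seealso [predict_ebv()], [tidy.gs_ridge()], [glance.gs_ridge()]
#' @export
fit_ridge <- function(genotypes, y, sigma_e2, sigma_beta2,
                      center = NULL, method = c("auto", "primal", "dual")) {
  g <- as_dosage_matrix(genotypes)
  x <- g$x
  method <- match.arg(method)
  if (!is.numeric(y) || length(y) != nrow(x)) {
    abort("`y` must be numeric with one entry per row of `genotypes`.")
  }
  if (nrow(x) < 2L) abort("Need at least two training individuals.")
  check_number(sigma_e2, "sigma_e2", min = 0, strict = TRUE)
  check_number(sigma_beta2, "sigma_beta2", min = 0, strict = TRUE)
  center <- center %||% (if (!is.null(g$freqs)) 2 * g$freqs else colMeans(x))
  if (length(center) != ncol(x)) {
    abort("`center` must supply one offset per marker.")
  }

  lambda <- sigma_e2 / sigma_beta2
  z <- sweep(x, 2L, center, "-")
  yc <- y - mean(y)
  n <- nrow(z)
  p <- ncol(z)
  use_dual <- switch(method,
    auto = p > n,
    primal = FALSE,
    dual = TRUE
  )
  beta <- if (p == 0L) {
    numeric(0)
  } else if (use_dual) {
    kern <- tcrossprod(z)
    diag(kern) <- diag(kern) + lambda
    drop(crossprod(z, solve(kern, yc)))
  } else {
    gram <- crossprod(z)
    diag(gram) <- diag(gram) + lambda
    drop(solve(gram, crossprod(z, yc)))
  }
  structure(
    list(
      alpha = mean(y), beta = beta, lambda = lambda,
      sigma_e2 = sigma_e2, sigma_beta2 = sigma_beta2,
      center = center, method = if (use_dual) "dual" else "primal",
      n = n, p = p
    ),
    class = "gs_ridge"
  )
}

#' @export
print.gs_ridge <- function(x, ...) {
  cat(sprintf(
    "<gs_ridge> %d marker effect(s) from %d individual(s); lambda = %.4g (%s solve)\n",
    x$p, x$n, x$lambda, x$method
  ))
  invisible(x)
}

#' Estimated breeding values from a fitted ridge model
#'
#' EBV of individual i is the marker-effect-weighted sum of its (centered)
#' dosages, using the same centering offsets as in training; the constant
#' shift from centering leaves correlations and regression slopes untouched.
#'
#' @param model A [fit_ridge()] result.
#' @param genotypes Prediction-set `genotype_matrix` (or dosage matrix) over
#'   the same markers.
#' @return Named numeric vector of EBV.
#' @export
predict_ebv <- function(model, genotypes) {
  stopifnot(inherits(model, "gs_ridge"))
  x <- as_dosage_matrix(genotypes)$x
  if (ncol(x) != model$p) {
    abort(sprintf(
      "Genotypes have %d marker(s) but the model was fitted with %d.",
      ncol(x), model$p
    ))
  }
  ebv <- drop(sweep(x, 2L, model$center, "-") %*% model$beta)
  names(ebv) <- rownames(x)
  ebv
}

#' @export
predict.gs_ridge <- function(object, genotypes, ...) {
  predict_ebv(object, genotypes)
}

#' Tidy a fitted ridge model
#'
#' @param x A `gs_ridge` object.
#' @param ... Unused.
#' @return A tibble with one row per marker: `marker`, `estimate`, `center`.
#' @export
tidy.gs_ridge <- function(x, ...) {
  tibble::tibble(
    marker = seq_len(x$p),
    estimate = unname(x$beta),
    center = unname(x$center)
  )
}

#' One-row summary of a fitted ridge model
#'
#' @param x A `gs_ridge` object.
#' @param ... Unused.
#' @return A tibble with `n`, `p`, `lambda`, `sigma_e2`, `sigma_beta2`,
#'   `alpha`, `method`.
#' @export
glance.gs_ridge <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, lambda = x$lambda,
    sigma_e2 = x$sigma_e2, sigma_beta2 = x$sigma_beta2,
    alpha = x$alpha, method = x$method
  )
}

#' Export a fitted ridge model as tabular text
#'
#' Writes the per-marker effects (with centering offsets) and a one-row
#' header of model constants; [read_ridge()] restores the model.
#'
#' @param model A `gs_ridge`.
#' @param prefix File path prefix.
#' @return `prefix`, invisibly.
#' @export
write_ridge <- function(model, prefix) {
  stopifnot(inherits(model, "gs_ridge"))
  utils::write.table(glance(model), paste0(prefix, ".model.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(tidy(model), paste0(prefix, ".effects.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(prefix)
}

#' @rdname write_ridge
#' @export
read_ridge <- function(prefix) {
  info <- utils::read.table(paste0(prefix, ".model.tsv"),
    header = TRUE, sep = "\t"
  )
  eff <- utils::read.table(paste0(prefix, ".effects.tsv"),
    header = TRUE, sep = "\t"
  )
  structure(
    list(
      alpha = info$alpha, beta = eff$estimate, lambda = info$lambda,
      sigma_e2 = info$sigma_e2, sigma_beta2 = info$sigma_beta2,
      center = eff$center, method = info$method,
      n = info$n, p = info$p
    ),
    class = "gs_ridge"
  )
}
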