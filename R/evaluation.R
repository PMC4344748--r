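#' Accuracy of genomic prediction
#'
#' Pearson correlation between true and estimated breeding values in the
#' prediction set.
#'
#' @param tbv,ebv Numeric vectors of equal length (>= 3), neither constant.
#' @return The correlation.
#' @export
prediction_accuracy <- function(tbv, ebv) {
  check_tbv_ebv(tbv, ebv)
  cor(tbv, ebv)
}

#' Bias of genomic prediction
#'
#' Regression slope of TBV on EBV (`cov(tbv, ebv) / var(ebv)`). The desired
#' value is 1.0; slopes below 1 indicate over-dispersed (overestimated) EBV,
#' slopes above 1 underestimation.
#'
#' @inheritParams prediction_accuracy
#' @return The regression slope.
#' @export
prediction_bias <- function(tbv, ebv) {
  check_tbv_ebv(tbv, ebv)
  stats::cov(tbv, ebv) / var(ebv)
}

check_tbv_ebv <- function(tbv, ebv) {
  if (!is.numeric(tbv) || !is.numeric(ebv) || length(tbv) != length(ebv) ||
      length(tbv) < 3L) {
    abort("`tbv` and `ebv` must be numeric vectors of equal length >= 3.")
  }
  if (anyNA(tbv) || anyNA(ebv)) abort("TBV/EBV must not contain NA.")
  if (var(tbv) == 0 || var(ebv) == 0) {
    abort("Accuracy/bias are undefined when TBV or EBV is constant.")
  }
  invisible(NULL)
}

#' Selection intensity of truncation selection
#'
#' Standardized selection differential when the top proportion `p` of a
#' normal distribution is selected: `i = phi(z) / p` with `z` the upper-p
#' quantile (the infinite-population truncation form). `i(1) = 0` and `i`
#' increases as `p` shrinks. When the finite number of candidates is
#' supplied, the order-statistic correction is used instead: the mean of the
#' expected top `k = p * n` normal order statistics (Blom approximation),
#' which is slightly below the infinite form for moderate `n`.
#'
#' @param p Selected proportion(s) in (0, 1].
#' @param n_candidates Optional finite number of candidates; when given, the
#'   order-statistic intensity is returned.
#' @return Selection intensity (standard-deviation units).
#' @examples
#' selection_intensity(25 / 500) # ~2.06
#' selection_intensity(25 / 500, n_candidates = 500) # ~2.05
#' @export
selection_intensity <- function(p, n_candidates = NULL) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) ||
      any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  if (!is.null(n_candidates)) {
    n <- check_count(n_candidates, "n_candidates")
    return(vapply(p, function(pi) {
      k <- max(1L, as.integer(round(pi * n)))
      if (k >= n) {
        return(0)
      }
      mean(qnorm(1 - (seq_len(k) - 0.375) / (n + 0.25)))
    }, numeric(1)))
  }
  ifelse(p == 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Response to selection via the breeders' equation
#'
#' `R = i * accuracy` in units of genetic standard deviations, where the
#' selection intensity `i` corresponds to selecting `n_selected` individuals
#' from `n_candidates` (e.g. 25 future sires from the genotyped prediction
#' set). The whole prediction set is treated as the candidate pool.
#'
#' @param accuracy Prediction accuracy in \[-1, 1\].
#' @param n_candidates Size of the prediction set.
#' @param n_selected Number selected (0 < n_selected <= n_candidates).
#' @param finite Use the finite-population intensity correction
#'   (default FALSE, the infinite-population form).
#' @return Response to selection (genetic-standard-deviation units).
#' @examples
#' response_to_selection(0.54, 500, 25) # ~1.11
#' @export
response_to_selection <- function(accuracy, n_candidates, n_selected,
                                  finite = FALSE) {
  if (!is.numeric(accuracy) || anyNA(accuracy) ||
      any(abs(accuracy) > 1)) {
    abort("`accuracy` must lie in [-1, 1].")
  }
  n_candidates <- check_count(n_candidates, "n_candidates")
  n_selected <- check_count(n_selected, "n_selected")
  if (n_selected > n_candidates) {
    abort("`n_selected` cannot exceed `n_candidates`.")
  }
  i <- selection_intensity(
    n_selected / n_candidates,
    n_candidates = if (finite) n_candidates else NULL
  )
  i * accuracy
}

#' Evaluate a prediction set
#'
#' Convenience wrapper computing accuracy and bias (and, when `n_selected` is
#' given, selection intensity and response to selection) as a one-row tibble.
#'
#' @inheritParams prediction_accuracy
#' @param n_selected Optional number of selected individuals for the
#'   breeders'-equation response.
#' @return A one-row tibble with columns `n`, `accuracy`, `bias`, and (if
#'   requested) `selected_proportion`, `intensity`, `response`.
#' @export
evaluate_prediction <- function(tbv, ebv, n_selected = NULL) {
  acc <- prediction_accuracy(tbv, ebv)
  out <- tibble::tibble(
    n = length(tbv),
    accuracy = acc,
    bias = prediction_bias(tbv, ebv)
  )
  if (!is.null(n_selected)) {
    n_selected <- check_count(n_selected, "n_selected")
    p <- n_selected / length(tbv)
    out$selected_proportion <- p
    out$intensity <- selection_intensity(p)
    out$response <- out$intensity * acc
  }
  out
}
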