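#' Define a genetic map
#'
#' A genetic map records the number of chromosomes and their genetic (cM) and
#' physical (bp) lengths. The default follows the simulated cattle-like genome
#' used throughout the package: 30 chromosomes, each 100 cM long and spanning
#' 1e8 bp, so that 1 cM corresponds to 1 Mbp.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param length_cM Genetic length per chromosome in centiMorgans. Recycled to
#'   `n_chromosomes`.
#' @param length_bp Physical length per chromosome in base pairs. Recycled to
#'   `n_chromosomes`.
#'
#' @return A tibble of class `genetic_map` with columns `chrom`, `length_cM`,
#'   and `length_bp`, one row per chromosome.
#' @examples
#' genetic_map()
#' genetic_map(n_chromosomes = 5, length_cM = 20, length_bp = 2e7)
#' @export
genetic_map <- function(n_chromosomes = 30, length_cM = 100, length_bp = 1e8) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  if (any(length_cM < 0) || any(length_bp <= 0)) {
    abort("Chromosome lengths must be positive (0 cM is allowed).")
  }
  map <- tibble::tibble(
    chrom = seq_len(n_chromosomes),
    length_cM = rep_len(as.numeric(length_cM), n_chromosomes),
    length_bp = rep_len(as.numeric(length_bp), n_chromosomes)
  )
  class(map) <- c("genetic_map", class(map))
  map
}

#' Piecewise-linear effective population size history
#'
#' Encodes an effective population size (Ne) that changes linearly between
#' anchor points placed back in time. The default reproduces a declining
#' Holstein-like history: Ne = 100 now, 1256 at 1000 years ago, 4350 at
#' 10 000 years ago, and 43 500 at 100 000 years ago.
#'
#' @param time_ago Strictly increasing anchor times, in years before present.
#' @param ne Effective population size at each anchor; all positive.
#' @param generation_interval Years per generation used to convert the anchor
#'   times to generations (default 1).
#'
#' @return An object of class `ne_schedule`.
#' @seealso [ne_at()] to interpolate, [sim_haplotype_panel()] which consumes
#'   the schedule.
#' @examples
#' ne_schedule()
#' ne_at(ne_schedule(), c(0, 500, 1000))
#' @export
ne_schedule <- function(time_ago = c(0, 1e3, 1e4, 1e5),
                        ne = c(100, 1256, 4350, 43500),
                        generation_interval = 1) {
  if (length(time_ago) != length(ne) || length(ne) < 1L) {
    abort("`time_ago` and `ne` must have equal, positive length.")
  }
  if (is.unsorted(time_ago, strictly = TRUE)) {
    abort("`time_ago` must be strictly increasing.")
  }
  if (any(ne <= 0)) abort("All `ne` values must be positive.")
  check_number(generation_interval, "generation_interval", min = 0, strict = TRUE)
  structure(
    list(
      time_ago = as.numeric(time_ago),
      ne = as.numeric(ne),
      generation_interval = as.numeric(generation_interval)
    ),
    class = "ne_schedule"
  )
}

#' Interpolate effective population size at given times
#'
#' Linear interpolation between the schedule's anchors; times beyond the last
#' anchor return the oldest Ne, times before the first anchor the most recent.
#'
#' @param schedule An [ne_schedule()].
#' @param time_ago Numeric vector of times (years before present).
#' @return Numeric vector of Ne values.
#' @export
ne_at <- function(schedule, time_ago) {
  stopifnot(inherits(schedule, "ne_schedule"))
  stats::approx(
    x = schedule$time_ago, y = schedule$ne, xout = time_ago,
    method = "linear", rule = 2
  )$y
}

#' @export
print.ne_schedule <- function(x, ...) {
  cat("<ne_schedule>", length(x$time_ago), "anchors;",
      x$generation_interval, "year(s)/generation\n")
  print(tibble::tibble(time_ago = x$time_ago, ne = x$ne))
  invisible(x)
}
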