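#' Import an ms/MaCS-style haplotype panel
#'
#' Reads the classic `ms` text layout so that genuine coalescent output (ms,
#' MaCS, msprime's `ms` export) can feed the pipeline for full-scale runs.
#' Each replicate block (`//` ... `segsites:` ... `positions:` ... haplotype
#' rows of 0/1) is mapped, in order, onto one chromosome of the supplied
#' genetic map; the fractional `positions` are rescaled to that chromosome's
#' cM and bp lengths. Sites monomorphic across the haplotypes are dropped with
#' a warning reporting the count.
#'
#' @param input Path to an ms-format text file, or a character vector of its
#'   lines.
#' @param map A [genetic_map()] with at least as many chromosomes as there are
#'   replicate blocks.
#'
#' @return A [haplotype_panel()].
#' @examples
#' lines <- c(
#'   "ms 4 1", "1 2 3", "", "//", "segsites: 2",
#'   "positions: 0.2 0.8", "01", "01", "00", "11"
#' )
#' read_ms_panel(lines, genetic_map(1, 100, 1e8))
#' @export
read_ms_panel <- function(input, map) {
  stopifnot(inherits(map, "genetic_map"))
  lines <- if (length(input) == 1L && file.exists(input)) {
    readLines(input)
  } else {
    as.character(input)
  }

  starts <- grep("^//", lines)
  if (length(starts) == 0L) {
    # Tolerate a bare block without the "//" marker.
    if (!any(grepl("^segsites:", lines))) {
      abort("No ms replicate blocks found (missing `//` / `segsites:` lines).")
    }
    starts <- grep("^segsites:", lines)[1] - 1L
  }
  if (length(starts) > nrow(map)) {
    abort(sprintf(
      "Input has %d replicate blocks but `map` has only %d chromosome(s).",
      length(starts), nrow(map)
    ))
  }
  ends <- c(starts[-1] - 1L, length(lines))

  blocks <- purrr::pmap(
    list(starts, ends, seq_along(starts)),
    function(from, to, b) {
      parse_ms_block(lines, from, to, map$chrom[b],
                     map$length_cM[b], map$length_bp[b])
    }
  )
  n_hap <- unique(vapply(blocks, function(b) nrow(b$haplotypes), integer(1)))
  if (length(n_hap) != 1L) {
    abort("Replicate blocks carry different numbers of haplotypes.")
  }

  hap <- do.call(cbind, purrr::map(blocks, "haplotypes"))
  sites <- purrr::list_rbind(purrr::map(blocks, "sites"))

  mono <- colMeans(hap)
  drop <- which(mono <= 0 | mono >= 1)
  if (length(drop) > 0L) {
    warn(sprintf("Dropped %d monomorphic site(s) from the imported panel.",
                 length(drop)))
    hap <- hap[, -drop, drop = FALSE]
    sites <- sites[-drop, , drop = FALSE]
  }
  if (ncol(hap) == 0L) abort("No segregating sites remain after import.")
  haplotype_panel(hap, sites, map)
}

parse_ms_block <- function(lines, from, to, chrom, len_cM, len_bp) {
  block <- lines[from:to]
  seg_i <- grep("^segsites:", block)
  pos_i <- grep("^positions:", block)
  if (length(seg_i) != 1L || length(pos_i) != 1L) {
    abort(sprintf(
      "Block starting at line %d lacks a single segsites:/positions: pair.",
      from
    ))
  }
  segsites <- as.integer(sub("^segsites:\\s*", "", block[seg_i]))
  pos <- as.numeric(strsplit(
    trimws(sub("^positions:\\s*", "", block[pos_i])), "\\s+"
  )[[1]])
  if (anyNA(pos) || length(pos) != segsites) {
    abort(sprintf(
      "Line %d: positions count (%d) does not match segsites (%d).",
      from + pos_i - 1L, length(pos), segsites
    ))
  }
  hap_lines <- block[seq(pos_i + 1L, length(block))]
  hap_lines <- hap_lines[nzchar(trimws(hap_lines))]
  hap <- parse_haplotype_lines(hap_lines, offset = from + pos_i - 1L)
  if (ncol(hap) != segsites) {
    abort(sprintf(
      "Block starting at line %d: haplotype length %d does not match segsites %d.",
      from, ncol(hap), segsites
    ))
  }
  # ms positions are fractions of the simulated segment. Break position ties
  # minimally so within-chromosome ordering is strict.
  pos_cM <- pos * len_cM
  dup <- duplicated(pos_cM)
  while (any(dup)) {
    pos_cM[dup] <- pos_cM[dup] + len_cM * 1e-9
    o <- order(pos_cM)
    pos_cM <- pos_cM[o]
    hap <- hap[, o, drop = FALSE]
    dup <- duplicated(pos_cM)
  }
  list(
    haplotypes = hap,
    sites = tibble::tibble(
      chrom = chrom, pos_cM = pos_cM, pos_bp = pos_cM / len_cM * len_bp
    )
  )
}
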