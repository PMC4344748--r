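#' Construct a base haplotype panel
#'
#' Bundles a 0/1 haplotype matrix (rows = haplotypes, columns = segregating
#' sites) with its site table and genetic map. Every site must be segregating
#' in the panel, the haplotype count must be even (the panel represents a
#' diploid-compatible pool), and site positions must increase strictly within
#' each chromosome.
#'
#' @param haplotypes Integer matrix of 0/1 allele codes, one row per haplotype
#'   and one column per segregating site.
#' @param sites Data frame with one row per site and columns `chrom`,
#'   `pos_cM`, `pos_bp`.
#' @param map A [genetic_map()] covering every chromosome in `sites`.
#'
#' @return An object of class `haplotype_panel` with elements `haplotypes`,
#'   `sites` (a tibble gaining a `base_freq` column, the frequency of the
#'   allele coded 1 computed over the panel), and `map`.
#' @seealso [sim_haplotype_panel()], [read_ms_panel()], [write_panel()]
#' @export
haplotype_panel <- function(haplotypes, sites, map) {
  if (!is.matrix(haplotypes)) abort("`haplotypes` must be a matrix.")
  storage.mode(haplotypes) <- "integer"
  if (anyNA(haplotypes) || !all(haplotypes == 0L | haplotypes == 1L)) {
    abort("`haplotypes` must contain only 0/1 allele codes.")
  }
  if (nrow(haplotypes) < 2L || nrow(haplotypes) %% 2L != 0L) {
    abort("The panel needs an even number of haplotypes (>= 2).")
  }
  sites <- tibble::as_tibble(sites)
  if (!all(c("chrom", "pos_cM", "pos_bp") %in% names(sites))) {
    abort("`sites` needs columns `chrom`, `pos_cM`, `pos_bp`.")
  }
  if (nrow(sites) != ncol(haplotypes)) {
    abort("`sites` must have one row per haplotype column.")
  }
  stopifnot(inherits(map, "genetic_map"))
  if (!all(sites$chrom %in% map$chrom)) {
    abort("Every site must lie on a chromosome of `map`.")
  }
  len <- map$length_cM[match(sites$chrom, map$chrom)]
  if (any(sites$pos_cM < 0) || any(sites$pos_cM > len)) {
    abort("Site positions must fall within their chromosome's length.")
  }
  split_pos <- split(sites$pos_cM, sites$chrom)
  if (any(vapply(split_pos, is.unsorted, logical(1), strictly = TRUE))) {
    abort("Site positions must be strictly increasing within each chromosome.")
  }
  freq <- colMeans(haplotypes)
  if (any(freq <= 0) || any(freq >= 1)) {
    abort("Every site must be segregating in the panel (0 < frequency < 1).")
  }
  sites$site <- seq_len(nrow(sites))
  sites$base_freq <- freq
  sites <- sites[, c("site", "chrom", "pos_cM", "pos_bp", "base_freq")]
  structure(
    list(haplotypes = haplotypes, sites = sites, map = map),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d haplotypes x %d segregating sites on %d chromosome(s)\n",
    nrow(x$haplotypes), ncol(x$haplotypes), nrow(x$map)
  ))
  cat(sprintf(
    "  allele-1 frequency: min %.4f / median %.4f / max %.4f\n",
    min(x$sites$base_freq), stats::median(x$sites$base_freq),
    max(x$sites$base_freq)
  ))
  invisible(x)
}

#' Number of haplotypes and sites in a panel
#' @param panel A [haplotype_panel()].
#' @return Integer vector `c(haplotypes, sites)`.
#' @export
panel_dim <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  dim(panel$haplotypes)
}

#' Checkpoint a haplotype panel as plain text
#'
#' Writes (or reads back) a panel as three plain-text files sharing a prefix:
#' `<prefix>.map.tsv` (chromosome lengths), `<prefix>.sites.tsv` (site table),
#' and `<prefix>.hap.txt` (one 0/1 string per haplotype). The round trip is
#' lossless.
#'
#' @param panel A [haplotype_panel()].
#' @param prefix File path prefix (directories must exist).
#' @return `write_panel()` returns `prefix` invisibly; `read_panel()` returns
#'   the reconstructed [haplotype_panel()].
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "haplotype_panel"))
  utils::write.table(panel$map, paste0(prefix, ".map.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(
    panel$sites[, c("chrom", "pos_cM", "pos_bp")],
    paste0(prefix, ".sites.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  writeLines(
    apply(panel$haplotypes, 1L, paste, collapse = ""),
    paste0(prefix, ".hap.txt")
  )
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map.tsv"), header = TRUE, sep = "\t")
  map <- genetic_map(
    n_chromosomes = nrow(map),
    length_cM = map$length_cM, length_bp = map$length_bp
  )
  sites <- utils::read.table(paste0(prefix, ".sites.tsv"), header = TRUE, sep = "\t")
  lines <- readLines(paste0(prefix, ".hap.txt"))
  hap <- parse_haplotype_lines(lines)
  haplotype_panel(hap, sites, map)
}

# Turn equal-length 0/1 strings into an integer matrix; errors name the first
# offending line.
parse_haplotype_lines <- function(lines, offset = 0L) {
  if (length(lines) == 0L) abort("No haplotype lines found.")
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf(
      "Haplotype line %d has length %d, expected %d.",
      bad + offset, widths[bad], widths[1]
    ))
  }
  bad <- grep("[^01]", lines)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Haplotype line %d contains characters other than 0/1.", bad[1] + offset
    ))
  }
  mat <- matrix(
    as.integer(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE)),
    nrow = length(lines), byrow = TRUE
  )
  mat
}
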