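#' Build a genetic map for the simulator
#'
#' Defines chromosomes in centiMorgans and evenly spaced marker positions.
#' Defaults mimic a pea-sized genome at GBS marker density before quality
#' filtering: 7 chromosomes of 100 cM each.
#'
#' @param n_chrom Number of chromosomes.
#' @param length_cM Chromosome length(s) in centiMorgans; recycled to
#'   `n_chrom`.
#' @param markers_per_chrom Marker count per chromosome; recycled.
#' @return A data frame with columns `marker`, `chrom`, `pos` (cM), of class
#'   `genome_map`.
#' @examples
#' gm <- genome_map(n_chrom = 2, markers_per_chrom = 5)
#' @export
genome_map <- function(n_chrom = 7, length_cM = 100, markers_per_chrom = 300) {
  stopifnot(n_chrom >= 1)
  length_cM <- rep_len(length_cM, n_chrom)
  markers_per_chrom <- rep_len(markers_per_chrom, n_chrom)
  if (any(markers_per_chrom < 1)) stop("need >= 1 marker per chromosome")
  chrom <- rep(paste0("chr", seq_len(n_chrom)), markers_per_chrom)
  pos <- unlist(lapply(seq_len(n_chrom), function(i) {
    m <- markers_per_chrom[i]
    if (m == 1) length_cM[i] / 2 else seq(0, length_cM[i], length.out = m)
  }))
  map <- data.frame(
    marker = sprintf("m_%s_%04d", chrom, unlist(lapply(markers_per_chrom, seq_len))),
    chrom = chrom,
    pos = pos,
    stringsAsFactors = FALSE
  )
  class(map) <- c("genome_map", "data.frame")
  validate_genome_map(map)
  map
}

validate_genome_map <- function(map) {
  if (nrow(map) == 0L) stop("no markers")
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  if (any(map$pos < 0)) stop("marker positions must be non-negative")
  by_chr <- split(map$pos, map$chrom)
  if (any(vapply(by_chr, function(p) is.unsorted(p), logical(1)))) {
    stop("marker positions must be non-decreasing within chromosome")
  }
  invisible(map)
}

#' Haldane map function
#'
#' Recombination fraction for a map distance under no interference:
#' r = (1 - exp(-2 d / 100)) / 2 with `d` in centiMorgans.
#'
#' @param d_cM Map distance(s) in centiMorgans.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}

# Deterministic sub-seed derivation from a master seed (kept < 2^31).
sub_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}
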