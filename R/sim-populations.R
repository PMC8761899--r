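#' Genotype matrix container
#'
#' Lines x markers allele-dosage matrix (copies of the alternate allele,
#' coded 0/1/2, `NA` for missing) with marker map and line metadata.
#' Residual heterozygotes in F6-derived material are kept as dosage 1.
#'
#' @param geno Integer matrix, lines in rows, markers in columns; dimnames
#'   required.
#' @param map Data frame with columns `marker`, `chrom`, `pos` matching the
#'   columns of `geno`.
#' @param lines Data frame with columns `line`, `population` matching the rows
#'   of `geno`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, map, lines) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  stopifnot(identical(colnames(geno), map$marker))
  stopifnot(identical(rownames(geno), lines$line))
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype values must be 0, 1, 2 or NA")
  structure(list(geno = geno, map = map, lines = lines), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf(
    "geno_matrix: %d lines x %d markers (%d chromosomes), %.1f%% missing\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom)), 100 * miss
  ))
  tab <- table(x$lines$population)
  cat("populations:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Simulate three homozygous parental genomes
#'
#' Draws parental alleles marker by marker so that the realized pairwise
#' divergence (fraction of markers at which two parents differ) matches the
#' requested fractions in expectation. Internally each marker is assigned one
#' of four patterns — all parents equal, or exactly one parent carrying the
#' divergent allele — with probabilities solved from the three pairwise
#' divergences.
#'
#' @param map A `genome_map`.
#' @param divergences Numeric length-3 vector of pairwise divergence fractions
#'   in order (1-2, 1-3, 2-3), each in \[0, 1\] and satisfying the triangle
#'   constraints of the pattern model.
#' @param seed Optional integer seed.
#' @return A 3 x markers integer matrix of alleles (0/1), rows named
#'   `P1`, `P2`, `P3`, with the map attached as attribute `map`.
#' @export
simulate_parents <- function(map, divergences, seed = NULL) {
  validate_genome_map(map)
  stopifnot(length(divergences) == 3, all(divergences >= 0), all(divergences <= 1))
  d12 <- divergences[1]; d13 <- divergences[2]; d23 <- divergences[3]
  q <- c(
    p1 = (d12 + d13 - d23) / 2,
    p2 = (d12 + d23 - d13) / 2,
    p3 = (d13 + d23 - d12) / 2
  )
  if (any(q < -1e-12) || sum(q) > 1 + 1e-12) {
    stop("divergences violate the single-divergent-parent pattern model")
  }
  q <- pmax(q, 0)
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(map)
  pattern <- sample.int(4L, M, replace = TRUE, prob = c(q, 1 - sum(q)))
  base <- sample(c(0L, 1L), M, replace = TRUE)
  P <- rbind(P1 = base, P2 = base, P3 = base)
  for (k in 1:3) {
    idx <- pattern == k
    P[k, idx] <- 1L - P[k, idx]
  }
  colnames(P) <- map$marker
  attr(P, "map") <- map
  P
}

#' Realized pairwise divergence between parents
#' @param parents Output of [simulate_parents()].
#' @return Named numeric vector of the three pairwise marker-difference
#'   fractions.
#' @export
parent_divergence <- function(parents) {
  c(
    d12 = mean(parents[1, ] != parents[2, ]),
    d13 = mean(parents[1, ] != parents[3, ]),
    d23 = mean(parents[2, ] != parents[3, ])
  )
}

# One meiotic gamete per line, vectorized over lines.
# h1, h2: n x M haplotype allele matrices; returns an n x M gamete matrix.
meiosis_gamete <- function(h1, h2, map) {
  n <- nrow(h1)
  M <- ncol(h1)
  state <- matrix(0L, n, M)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    m <- length(idx)
    init <- matrix(stats::rbinom(n, 1L, 0.5), n, 1)
    if (m > 1) {
      r <- haldane_r(diff(map$pos[idx]))
      flips <- matrix(
        stats::rbinom(n * (m - 1), 1L, rep(r, each = n)),
        n, m - 1
      )
      cs <- cbind(init, flips)
      # cumulative xor along the chromosome = parity of cumulative flips
      state[, idx] <- t(apply(cs, 1, cumsum)) %% 2L
    } else {
      state[, idx] <- init
    }
  }
  h1 * (1L - state) + h2 * state
}

#' Simulate a recombinant inbred line population
#'
#' Lines descend from the F1 of two homozygous parents by `generations`
#' rounds of selfing with single-seed descent. Meiosis assumes no
#' interference; recombination fractions follow the Haldane map function.
#' Expected residual heterozygosity per marker after g generations is 0.5^g.
#'
#' @param p1,p2 Parental allele vectors (0/1) over the map's markers.
#' @param n_lines Number of lines to derive.
#' @param generations Selfing generations after the F1 (default 6, i.e.
#'   F2..F7 single-seed descent yielding F6-derived-like lines).
#' @param map A `genome_map`.
#' @param seed Optional integer seed.
#' @param population Population label for the line metadata.
#' @return A [geno_matrix()] with dosage = copies of the alternate (allele 1)
#'   allele.
#' @export
simulate_ril_population <- function(p1, p2, n_lines, generations = 6, map,
                                    seed = NULL, population = "pop") {
  validate_genome_map(map)
  stopifnot(n_lines >= 2, generations >= 1)
  stopifnot(length(p1) == nrow(map), length(p2) == nrow(map))
  if (all(p1 == p2)) warning("monomorphic population: parents identical at all markers")
  if (!is.null(seed)) set.seed(seed)
  h1 <- matrix(rep(as.integer(p1), each = n_lines), n_lines, nrow(map))
  h2 <- matrix(rep(as.integer(p2), each = n_lines), n_lines, nrow(map))
  for (g in seq_len(generations)) {
    g1 <- meiosis_gamete(h1, h2, map)
    g2 <- meiosis_gamete(h1, h2, map)
    h1 <- g1
    h2 <- g2
  }
  geno <- h1 + h2
  rownames(geno) <- sprintf("%s_%03d", population, seq_len(n_lines))
  colnames(geno) <- map$marker
  geno_matrix(
    geno,
    map,
    data.frame(line = rownames(geno), population = population,
               stringsAsFactors = FALSE)
  )
}

#' Simulate the three connected RIL populations of the study design
#'
#' Three populations from paired crosses among three homozygous parents
#' (one parent configured as more divergent, mirroring an exotic founder).
#' Population sizes default to 102, 100 and 104 lines.
#'
#' @param map A `genome_map`.
#' @param sizes Integer length-3 population sizes.
#' @param divergences Pairwise parent divergences (1-2, 1-3, 2-3). The default
#'   makes parent 3 more distant from parents 1 and 2 than those are from
#'   each other.
#' @param generations Selfing generations (default 6).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return A [geno_matrix()] combining the three populations (`P1xP2`,
#'   `P3xP1`, `P3xP2`), with the parent matrix attached as attribute
#'   `parents`.
#' @export
simulate_study_panel <- function(map = genome_map(),
                                 sizes = c(102, 100, 104),
                                 divergences = c(0.30, 0.45, 0.45),
                                 generations = 6,
                                 seed = 1) {
  stopifnot(length(sizes) == 3, all(sizes >= 2))
  parents <- simulate_parents(map, divergences, seed = sub_seed(seed, 1))
  crosses <- list(
    AxI = c(1, 2),  # parents 1 x 2
    KxA = c(3, 1),  # parent 3 x parent 1
    KxI = c(3, 2)   # parent 3 x parent 2
  )
  pops <- lapply(seq_along(crosses), function(i) {
    pr <- crosses[[i]]
    simulate_ril_population(
      parents[pr[1], ], parents[pr[2], ], n_lines = sizes[i],
      generations = generations, map = map,
      seed = sub_seed(seed, 1 + i), population = names(crosses)[i]
    )
  })
  geno <- do.call(rbind, lapply(pops, function(p) p$geno))
  lines <- do.call(rbind, lapply(pops, function(p) p$lines))
  out <- geno_matrix(geno, map, lines)
  attr(out, "parents") <- parents
  out
}

#' Overlay missing calls on a genotype matrix
#'
#' Each entry is set missing independently with probability
#' 1 - (1 - mpm_j)(1 - mps_i), combining a per-marker and a per-sample
#' missingness rate, emulating GBS coverage structure. Observed entries are
#' never altered.
#'
#' @param G A [geno_matrix()].
#' @param mpm_profile Per-marker missing rate(s), scalar or length = markers.
#' @param mps_profile Per-sample missing rate(s), scalar or length = lines.
#' @param seed Optional integer seed (same seed, same mask).
#' @return A `geno_matrix` with `NA`s inserted.
#' @export
add_missingness <- function(G, mpm_profile = 0, mps_profile = 0, seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  pm <- rep_len(mpm_profile, ncol(G$geno))
  ps <- rep_len(mps_profile, nrow(G$geno))
  stopifnot(all(pm >= 0), all(pm <= 1), all(ps >= 0), all(ps <= 1))
  prob <- 1 - outer(1 - ps, 1 - pm)
  if (all(prob >= 1)) stop("no data left: all entries would be missing")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(length(prob)) < prob, nrow(prob), ncol(prob))
  geno <- G$geno
  geno[mask] <- NA
  geno_matrix(geno, G$map, G$lines)
}
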