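#' Write a genotype matrix as VCF v4.2
#'
#' Biallelic SNP records with a GT field; dosage 0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, missing -> ./. . Positions are the map's centiMorgan positions
#' scaled to integer coordinates.
#'
#' @param G A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rilgs",
    sprintf("##contig=<ID=%s>", unique(G$map$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$lines$line), collapse = "\t")
  )
  gt <- matrix("./.", nrow(G$geno), ncol(G$geno))
  obs <- !is.na(G$geno)
  gt[obs] <- gt_codes[G$geno[obs] + 1L]
  body <- paste(
    G$map$chrom,
    as.integer(round(G$map$pos * 1e4)) + 1L,
    G$map$marker,
    "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses with `vcfR`; keeps biallelic SNP records only (multiallelic
#' records are skipped and counted), and codes genotypes as alternate-allele
#' dosage: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA. Phased separators
#' are accepted. Population labels are taken from the sample-name prefix
#' before the first underscore when every sample has one, else a single
#' population is assumed.
#'
#' @param path VCF file path.
#' @param populations Optional explicit line -> population character vector
#'   (named by line).
#' @return A [geno_matrix()]; the number of skipped multiallelic records is
#'   attached as attribute `n_multiallelic_skipped`.
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("malformed or empty VCF: no records")
  bi <- vcfR::is.biallelic(v)
  n_skip <- sum(!bi)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- sub(":.*", "", x)
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  geno <- t(apply(gt, 1, code))
  dimnames(geno) <- dimnames(gt)
  geno <- t(geno)  # lines x markers
  ids <- v@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(v@fix[is.na(ids) | ids == ".", "CHROM"],
                                         "_", v@fix[is.na(ids) | ids == ".", "POS"])
  map <- data.frame(
    marker = ids,
    chrom = v@fix[, "CHROM"],
    pos = as.numeric(v@fix[, "POS"]),
    stringsAsFactors = FALSE
  )
  colnames(geno) <- map$marker
  line_ids <- rownames(geno)
  pop <- if (!is.null(populations)) {
    unname(populations[line_ids])
  } else if (all(grepl("_", line_ids))) {
    sub("_.*", "", line_ids)
  } else {
    rep("pop1", length(line_ids))
  }
  out <- geno_matrix(geno, map,
                     data.frame(line = line_ids, population = pop,
                                stringsAsFactors = FALSE))
  attr(out, "n_multiallelic_skipped") <- n_skip
  out
}

#' Marker quality filtering
#'
#' Applies, in order: (1) remove markers whose missing fraction exceeds
#' `mpm`; (2) remove monomorphic markers; (3) remove markers with minor
#' allele frequency below `maf_min`, computed on non-missing calls with
#' heterozygotes contributing one allele copy (allele frequency =
#' mean(dosage)/2).
#'
#' @param G A [geno_matrix()].
#' @param mpm Maximum allowed missing fraction per marker (default 0.2).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @return List with `geno` (filtered `geno_matrix`) and `report` (class
#'   `filter_report`): removal counts per rule and thresholds used.
#' @export
filter_markers <- function(G, mpm = 0.2, maf_min = 0.05) {
  stopifnot(inherits(G, "geno_matrix"), mpm >= 0, mpm <= 1,
            maf_min >= 0, maf_min <= 0.5)
  n0 <- ncol(G$geno)
  miss <- colMeans(is.na(G$geno))
  keep1 <- miss <= mpm
  n_miss <- sum(!keep1)
  g1 <- G$geno[, keep1, drop = FALSE]
  mono <- apply(g1, 2, function(x) {
    u <- unique(x[!is.na(x)])
    length(u) <= 1
  })
  n_mono <- sum(mono)
  g2 <- g1[, !mono, drop = FALSE]
  p <- colMeans(g2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep3 <- maf >= maf_min
  n_maf <- sum(!keep3)
  kept <- colnames(g2)[keep3]
  report <- structure(list(
    axis = "marker", input = n0,
    removed_missing = n_miss, removed_monomorphic = n_mono,
    removed_maf = n_maf, retained = length(kept),
    thresholds = c(mpm = mpm, maf_min = maf_min)
  ), class = "filter_report")
  if (length(kept) == 0L) {
    stop("all markers removed by filtering (missing: ", n_miss,
         ", monomorphic: ", n_mono, ", MAF: ", n_maf, ")")
  }
  sel <- match(kept, G$map$marker)
  out <- geno_matrix(G$geno[, kept, drop = FALSE], G$map[sel, , drop = FALSE],
                     G$lines)
  list(geno = out, report = report)
}

#' Sample (line) filtering by missing rate
#'
#' Removes lines whose missing fraction exceeds `mps`. Intended to run after
#' [filter_markers()] (markers first, then samples). A warning flag is set in
#' the report when any population drops below 2 lines.
#'
#' @param G A [geno_matrix()] (typically marker-filtered).
#' @param mps Maximum allowed missing fraction per line (default 0.25).
#' @return List with `geno` and `report` as in [filter_markers()].
#' @export
filter_samples <- function(G, mps = 0.25) {
  stopifnot(inherits(G, "geno_matrix"), mps >= 0, mps <= 1)
  miss <- rowMeans(is.na(G$geno))
  keep <- miss <= mps
  lines <- G$lines[keep, , drop = FALSE]
  small <- names(which(table(lines$population) < 2))
  if (length(small)) {
    warning("population(s) reduced below 2 lines: ",
            paste(small, collapse = ", "))
  }
  report <- structure(list(
    axis = "sample", input = nrow(G$geno),
    removed_missing = sum(!keep), retained = sum(keep),
    thresholds = c(mps = mps),
    small_populations = small
  ), class = "filter_report")
  if (!any(keep)) stop("all samples removed by filtering")
  out <- geno_matrix(G$geno[keep, , drop = FALSE], G$map, lines)
  list(geno = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report (%s): %d in, %d retained\n",
              x$axis, x$input, x$retained))
  for (nm in grep("^removed_", names(x), value = TRUE)) {
    cat(sprintf("  %s: %d\n", sub("removed_", "removed by ", nm), x[[nm]]))
  }
  invisible(x)
}

#' Impute missing genotype calls
#'
#' Observed entries are never altered. Methods:
#' \describe{
#'   \item{mode}{per-marker most frequent call; ties resolved toward the
#'     lower code.}
#'   \item{knn}{k nearest lines by mean absolute allele-dosage difference
#'     over shared non-missing markers; majority vote among neighbours with
#'     an observed call at the marker, ties (or no informative neighbour)
#'     resolved toward the per-marker mode.}
#' }
#'
#' @param G A [geno_matrix()] with no marker or line entirely missing.
#' @param method `"knn"` (default) or `"mode"`.
#' @param k Neighbours for knn (default 5).
#' @return A complete `geno_matrix`.
#' @export
impute_genotypes <- function(G, method = c("knn", "mode"), k = 5) {
  stopifnot(inherits(G, "geno_matrix"))
  method <- match.arg(method)
  geno <- G$geno
  if (!anyNA(geno)) return(G)
  if (any(colMeans(is.na(geno)) == 1)) stop("marker entirely missing")
  if (any(rowMeans(is.na(geno)) == 1)) stop("sample entirely missing")
  marker_mode <- apply(geno, 2, function(x) {
    tb <- table(factor(x, levels = 0:2))
    as.integer(names(tb)[which.max(tb)])  # which.max takes first = lower code
  })
  if (method == "mode") {
    for (j in seq_len(ncol(geno))) {
      nas <- is.na(geno[, j])
      geno[nas, j] <- marker_mode[j]
    }
  } else {
    n <- nrow(geno)
    # pairwise mean |dosage difference| over shared non-missing markers
    obs <- !is.na(geno)
    g0 <- geno
    g0[!obs] <- 0
    shared <- tcrossprod(obs * 1)
    # sum |gi - gj| decomposes via dosage levels; do it directly per pair
    d2 <- matrix(0, n, n)
    for (lev in 0:2) {
      A <- (g0 == lev & obs) * 1
      for (lev2 in 0:2) {
        B <- (g0 == lev2 & obs) * 1
        if (abs(lev - lev2) > 0) d2 <- d2 + abs(lev - lev2) * tcrossprod(A, B)
      }
    }
    D <- d2 / pmax(shared, 1)
    diag(D) <- Inf
    for (i in which(rowSums(!obs) > 0)) {
      nb <- order(D[i, ])[seq_len(min(k, n - 1))]
      for (j in which(!obs[i, ])) {
        votes <- geno[nb, j]
        votes <- votes[!is.na(votes)]
        if (length(votes) == 0) {
          geno[i, j] <- marker_mode[j]
        } else {
          tb <- table(factor(votes, levels = 0:2))
          top <- which(tb == max(tb))
          geno[i, j] <- if (length(top) > 1) {
            marker_mode[j]  # tie -> resolved toward mode
          } else {
            as.integer(names(tb)[top])
          }
        }
      }
    }
  }
  geno_matrix(geno, G$map, G$lines)
}
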