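#' Genotype-dosage matrix with variant metadata
#'
#' Container for an \eqn{n \times m} matrix of genotype dosages (expected
#' copies of the nonreference allele, values in \[0, 2\], possibly
#' non-integer after imputation) together with per-variant metadata.
#' Minor allele frequency (MAF) and the carrier count \eqn{\tilde{MAC}}
#' (number of individuals with dosage strictly greater than zero, the
#' carrier-count proxy for the minor allele count under imputed dosages)
#' are computed from the dosages on construction.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   values in \[0, 2\] or `NA`.
#' @param sample_ids character vector of length `nrow(dosages)`; defaults to
#'   rownames or `S1..Sn`.
#' @param variants data frame with one row per variant; columns `id`,
#'   `chrom`, `pos` (1-based, VCF convention) and optionally `functional`
#'   (simulation bookkeeping). Defaults are derived from column names.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids` and `variants` (the latter gaining computed
#'   `maf` and `mac_tilde` columns).
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, variants = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  rng <- range(dosages, na.rm = TRUE, finite = TRUE)
  if (m > 0L && any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2))
    stop("dosage values must lie in [0, 2] (or be NA)")
  if (is.null(sample_ids))
    sample_ids <- rownames(dosages) %||% paste0("S", seq_len(n))
  if (length(sample_ids) != n)
    stop("length(sample_ids) must equal nrow(dosages)")
  if (is.null(variants)) {
    variants <- data.frame(
      id = colnames(dosages) %||% paste0("v", seq_len(m)),
      chrom = rep("1", m),
      pos = seq_len(m),
      stringsAsFactors = FALSE
    )
  }
  variants <- as.data.frame(variants)
  if (nrow(variants) != m)
    stop("nrow(variants) must equal ncol(dosages)")
  if (is.null(variants$id)) variants$id <- colnames(dosages) %||% paste0("v", seq_len(m))
  if (is.null(variants$chrom)) variants$chrom <- "1"
  if (is.null(variants$pos)) variants$pos <- seq_len(m)
  if (is.null(variants$functional)) variants$functional <- FALSE
  variants$maf <- apply(dosages, 2L, function(x) {
    if (all(is.na(x))) NA_real_ else compute_maf(x)
  })
  variants$mac_tilde <- apply(dosages, 2L, function(x) {
    if (all(is.na(x))) NA_integer_ else compute_mac_tilde(x)
  })
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, sample_ids = sample_ids, variants = variants),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (ncol(x$dosages) > 0) {
    cat(sprintf("  MAF range: %.5g - %.5g; MAC~ range: %d - %d\n",
                min(x$variants$maf, na.rm = TRUE),
                max(x$variants$maf, na.rm = TRUE),
                min(x$variants$mac_tilde, na.rm = TRUE),
                max(x$variants$mac_tilde, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Carrier count of a dosage vector
#'
#' The number of individuals carrying any copy of the nonreference allele,
#' i.e. the count of non-missing dosages strictly greater than zero.  With
#' imputed dosages this is the natural proxy for the minor allele count at
#' low MAF, and is the quantity the type-1-error pooling groups on.
#'
#' @param dosage_column numeric vector of dosages in \[0, 2\], `NA` allowed.
#' @return Non-negative integer count.
#' @export
compute_mac_tilde <- function(dosage_column) {
  obs <- dosage_column[!is.na(dosage_column)]
  if (length(obs) == 0L) stop("all dosages missing: unusable variant")
  sum(obs > 0)
}

#' Minor allele frequency of a dosage vector
#'
#' Estimates the nonreference allele frequency as `mean(dosage)/2` over
#' non-missing samples and folds it to the minor allele:
#' `min(p, 1 - p)`.
#'
#' @inheritParams compute_mac_tilde
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(dosage_column) {
  obs <- dosage_column[!is.na(dosage_column)]
  if (length(obs) == 0L) stop("all dosages missing: unusable variant")
  p_hat <- mean(obs) / 2
  min(p_hat, 1 - p_hat)
}

#' Drop monomorphic variants
#'
#' Retains exactly the variants whose observed dosage column has at least
#' two distinct values and positive MAF; column order is preserved.
#' Idempotent.
#'
#' @param gm a [genotype_matrix].
#' @return A `genotype_matrix` with the polymorphic subset (possibly zero
#'   variants).
#' @export
filter_polymorphic <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- vapply(seq_len(ncol(gm$dosages)), function(j) {
    x <- gm$dosages[, j]
    obs <- x[!is.na(x)]
    length(obs) > 0L && length(unique(obs)) >= 2L && compute_maf(x) > 0
  }, logical(1))
  genotype_matrix(gm$dosages[, keep, drop = FALSE],
                  sample_ids = gm$sample_ids,
                  variants = gm$variants[keep,
                    setdiff(names(gm$variants), c("maf", "mac_tilde")),
                    drop = FALSE])
}

#' Partition variants into position-contiguous subregions
#'
#' Groups variants into `K` subregions that are contiguous in physical
#' position, for region-level collapsing tests.  The default rule is an
#' equal-count quantile cut of the position order; an explicit boundary
#' vector of subregion sizes overrides it (useful when subregions were
#' chosen by eye from an LD plot and only the resulting sizes are known).
#'
#' @param variants data frame with a `pos` column (and optionally `id`).
#' @param K number of subregions, `1 <= K <= nrow(variants)`.
#' @param sizes optional integer vector of length `K` giving the number of
#'   variants per subregion in position order; must sum to `nrow(variants)`.
#' @return An object of class `subregion_partition`: list with
#'   `assignments` (integer subregion label per variant, in input order)
#'   and `K`.
#' @export
partition_by_position <- function(variants, K, sizes = NULL) {
  variants <- as.data.frame(variants)
  m <- nrow(variants)
  if (K < 1L || K > m) stop("K must be between 1 and the number of variants")
  ord <- order(variants$pos)
  if (!is.null(sizes)) {
    if (length(sizes) != K) stop("length(sizes) must equal K")
    if (sum(sizes) != m) stop("sizes must sum to the number of variants")
    lab_sorted <- rep.int(seq_len(K), times = sizes)
  } else if (K == 1L) {
    lab_sorted <- rep(1L, m)
  } else {
    # equal-count quantile cut on position rank
    lab_sorted <- as.integer(cut(seq_len(m), breaks = K, labels = FALSE))
  }
  assignments <- integer(m)
  assignments[ord] <- lab_sorted
  structure(list(assignments = assignments, K = as.integer(K)),
            class = "subregion_partition")
}

#' @export
print.subregion_partition <- function(x, ...) {
  cat(sprintf("<subregion_partition> K = %d, sizes: %s\n", x$K,
              paste(tabulate(x$assignments, x$K), collapse = "/")))
  invisible(x)
}

#' Subset a genotype matrix by sample
#'
#' Row-subsets the dosage matrix; per-variant MAF and carrier counts are
#' recomputed on the retained samples.
#'
#' @param gm a [genotype_matrix].
#' @param mask logical or integer index over samples.
#' @return A `genotype_matrix`.
#' @export
subset_samples <- function(gm, mask) {
  stopifnot(inherits(gm, "genotype_matrix"))
  genotype_matrix(gm$dosages[mask, , drop = FALSE],
                  sample_ids = gm$sample_ids[mask],
                  variants = gm$variants[,
                    setdiff(names(gm$variants), c("maf", "mac_tilde")),
                    drop = FALSE])
}

#' Variant frequency class
#'
#' Classifies variants as rare (MAF < 1\%), low-frequency
#' (1\% <= MAF < 5\%) or common (MAF >= 5\%).
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param cutoffs length-2 numeric, the rare/low-frequency and
#'   low-frequency/common boundaries.
#' @return factor with levels `rare`, `low-frequency`, `common`.
#' @export
variant_class <- function(maf, cutoffs = c(0.01, 0.05)) {
  cut(maf, breaks = c(-Inf, cutoffs, Inf), right = FALSE,
      labels = c("rare", "low-frequency", "common"))
}
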