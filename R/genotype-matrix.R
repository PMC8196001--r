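#' Genotype matrix container
#'
#' Holds effect-allele dosages for `n` samples by `m` variants together with
#' per-variant metadata. Dosages are counts of the ALT (effect) allele in
#' `[0, 2]`; hard calls are the integers 0/1/2, imputed dosages may be
#' fractional. The effect allele is ALT throughout the package.
#'
#' @param dosage numeric `n x m` matrix of effect-allele dosages in `[0, 2]`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, and optionally `info` (imputation info score in `[0, 1]`).
#'   One row per column of `dosage`. `eaf` is recomputed from the dosages.
#' @param samples character vector of sample IDs (defaults to the row names
#'   of `dosage`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `variants` (including an `eaf` column) and `dosage`.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols))
    stop("variant metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop("variants has ", nrow(variants), " rows but dosage has ",
         ncol(dosage), " columns")
  if (anyDuplicated(variants$id))
    stop("duplicate variant IDs: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (length(samples) != nrow(dosage))
    stop("samples length does not match dosage rows")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
    stop("dosages must lie in [0, 2]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (is.null(variants$info)) variants$info <- NA_real_
  variants$eaf <- colMeans(dosage) / 2
  rownames(dosage) <- samples
  colnames(dosage) <- variants$id
  structure(list(samples = as.character(samples),
                 variants = variants,
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants\n")
  cat("  chrom:", paste(unique(x$variants$chrom), collapse = ","),
      " EAF range:", paste(signif(range(x$variants$eaf), 3), collapse = "-"),
      "\n")
  invisible(x)
}

#' Filter variants on minor allele frequency and imputation quality
#'
#' Keeps variants with `min(EAF, 1 - EAF) >= maf_min` and, where an info
#' score is available, `info >= info_min` (both boundaries inclusive).
#' Variants with no info score pass the info filter. Variant order is
#' preserved.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param info_min minimum imputation info score in `[0, 1]`.
#' @return the filtered `genotype_matrix`.
#' @export
filter_variants <- function(g, maf_min = 0.01, info_min = 0.3) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (info_min < 0 || info_min > 1) stop("info_min must be in [0, 1]")
  maf <- pmin(g$variants$eaf, 1 - g$variants$eaf)
  keep <- maf >= maf_min &
    (is.na(g$variants$info) | g$variants$info >= info_min)
  subset_variants(g, which(keep))
}

#' Positional subset of variants, preserving the order of `idx`
#' @param g a [genotype_matrix()].
#' @param idx integer positions of variants to keep.
#' @return the subset `genotype_matrix`.
#' @export
subset_variants <- function(g, idx) {
  genotype_matrix(g$dosage[, idx, drop = FALSE],
                  g$variants[idx, setdiff(names(g$variants), "eaf"),
                             drop = FALSE],
                  samples = g$samples)
}

#' Pairwise variant correlation (LD) matrix
#'
#' Pearson correlation of dosages; variants with zero variance yield zero
#' correlation to everything (and unit diagonal).
#'
#' @param g a [genotype_matrix()].
#' @return `m x m` correlation matrix with variant IDs as dimnames.
#' @export
ld_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$dosage
  sds <- apply(X, 2, stats::sd)
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  dimnames(R) <- list(g$variants$id, g$variants$id)
  R
}
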