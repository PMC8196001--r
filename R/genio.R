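#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file into a [genotype_matrix()]. Dosages are taken from
#' the FORMAT field named by `dosage_field_preference` when present
#' (default: `DS` if available, otherwise the GT allele count).
#' Multiallelic records are rejected with a warning. Missing genotypes are
#' mean-imputed per variant; per-variant missingness is reported in
#' `attr(, "missingness")`. Variants missing in all samples are dropped
#' with a warning. An imputation info score is read from the INFO keys
#' `INFO` or `R2` when present.
#'
#' @param path path to an uncompressed or gzipped VCF.
#' @param dosage_field_preference character vector ordering the FORMAT
#'   fields to try, from `c("DS", "GT")`.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, dosage_field_preference = c("DS", "GT")) {
  if (!file.exists(path)) stop("file not found: ", path)
  dosage_field_preference <- match.arg(dosage_field_preference,
                                       c("DS", "GT"), several.ok = TRUE)
  .validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) rejected: ",
            paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)

  fmt_keys <- strsplit(unname(v@gt[, "FORMAT"]), ":", fixed = TRUE)
  have_ds <- all(vapply(fmt_keys, function(k) "DS" %in% k, logical(1)))
  use_ds <- "DS" %in% dosage_field_preference && have_ds &&
    (match("DS", dosage_field_preference) <
       ifelse("GT" %in% dosage_field_preference,
              match("GT", dosage_field_preference), Inf) || !any(
                vapply(fmt_keys, function(k) "GT" %in% k, logical(1))))

  if (use_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    D <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(s) {
      out <- rep(NA_real_, length(s))
      ok <- !is.na(s) & !grepl("\\.", s)
      alleles <- strsplit(s[ok], "[/|]")
      out[ok] <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
      out
    }
    D <- t(apply(gt, 2, count_alt))
    if (nrow(fix) == 1) D <- matrix(D, ncol = 1,
                                    dimnames = list(colnames(v@gt)[-1], NULL))
  }

  miss <- colMeans(is.na(D))
  all_missing <- miss >= 1
  if (any(all_missing)) {
    warning(sum(all_missing), " variant(s) missing in all samples dropped: ",
            paste(utils::head(fix[all_missing, "ID"], 5), collapse = ", "))
    D <- D[, !all_missing, drop = FALSE]
    fix <- fix[!all_missing, , drop = FALSE]
    miss <- miss[!all_missing]
  }
  for (j in which(miss > 0)) {
    mj <- is.na(D[, j])
    D[mj, j] <- mean(D[!mj, j])
  }

  info_score <- .parse_info_score(fix[, "INFO"])
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"],
                         ref = fix[, "REF"],
                         alt = fix[, "ALT"],
                         info = info_score,
                         stringsAsFactors = FALSE)
  no_id <- is.na(variants$id) | variants$id == "."
  variants$id[no_id] <- paste0(variants$chrom[no_id], ":", variants$pos[no_id])
  g <- genotype_matrix(D, variants, samples = rownames(D))
  attr(g, "missingness") <- stats::setNames(miss, variants$id)
  g
}

.validate_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF (no #CHROM header line): ", path)
  nfield <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- seq(hdr[1] + 1L, length(lines))
  if (hdr[1] == length(lines)) return(invisible(TRUE))
  counts <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  nonempty <- nzchar(lines[body])
  bad <- which(nonempty & counts != nfield)
  if (length(bad))
    stop("malformed VCF: line ", body[bad[1]], " has ", counts[bad[1]],
         " fields, expected ", nfield)
  invisible(TRUE)
}

.parse_info_score <- function(info) {
  get_key <- function(s, key) {
    m <- regmatches(s, regexpr(paste0("(^|;)", key, "=[^;]+"), s))
    ifelse(lengths(m) > 0 | nzchar(m),
           suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "", m))),
           NA_real_)
  }
  out <- vapply(info, function(s) {
    if (is.na(s)) return(NA_real_)
    for (key in c("INFO", "R2", "DR2")) {
      m <- regmatches(s, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), s,
                                 perl = TRUE))
      if (length(m) && nzchar(m))
        return(suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "", m))))
    }
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Write genotypes to a plain-text VCF 4.2 file
#'
#' Hard calls (all dosages integer) are written as GT; fractional dosages
#' as DS. The info score, when present, is written as `INFO=<score>`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param field `"auto"` (GT when all dosages are integers, else DS),
#'   `"GT"` or `"DS"`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, field = c("auto", "GT", "DS")) {
  stopifnot(inherits(g, "genotype_matrix"))
  field <- match.arg(field)
  D <- g$dosage
  integral <- max(abs(D - round(D))) < 1e-9
  if (field == "auto") field <- if (integral) "GT" else "DS"
  if (field == "GT" && !integral)
    stop("cannot write fractional dosages as GT; use field = \"DS\"")
  v <- g$variants
  info <- ifelse(is.na(v$info), ".", paste0("INFO=", v$info))
  if (field == "GT") {
    codes <- c("0/0", "0/1", "1/1")
    body <- matrix(codes[round(t(D)) + 1L], nrow = ncol(D))
    fmt <- "GT"
  } else {
    body <- matrix(formatC(t(D), format = "g", digits = 6),
                   nrow = ncol(D))
    fmt <- "DS"
  }
  lines <- c("##fileformat=VCFv4.2",
             "##source=bilicausal",
             paste0("##INFO=<ID=INFO,Number=1,Type=Float,",
                    "Description=\"Imputation info score\">"),
             if (field == "GT")
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
             else
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"))
  rows <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, fmt,
                apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, rows), path)
  invisible(path)
}

.pheno_required <- c("sample_id", "bilirubin", "hypertension", "sex", "age",
                     "bmi", "t2d")

#' Read a phenotype/covariate table
#'
#' Tab-separated with header; requires columns `sample_id`, `bilirubin`,
#' `hypertension`, `sex`, `age`, `bmi`, `t2d`; any columns named `pc1`,
#' `pc2`, ... are kept as principal components. Binary columns must be
#' 0/1 or NA.
#'
#' @param path path to a TSV file.
#' @return data.frame of phenotypes.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  missing_cols <- setdiff(.pheno_required, names(d))
  if (length(missing_cols))
    stop("phenotype file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(d$sample_id) || any(!nzchar(d$sample_id)))
    stop("phenotype file has missing sample IDs")
  for (col in c("hypertension", "sex", "t2d")) {
    v <- d[[col]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("column '", col, "' must be 0/1 or NA")
  }
  d
}

#' Write a phenotype table as TSV
#' @param pheno data.frame with the columns of [read_phenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  missing_cols <- setdiff(.pheno_required, names(pheno))
  if (length(missing_cols))
    stop("phenotype table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  data.table::fwrite(as.data.frame(pheno)[, c(
    .pheno_required, setdiff(names(pheno), .pheno_required))],
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

.sumstat_cols <- c("chrom", "pos", "id", "ea", "oa", "eaf", "beta", "se", "p")

#' Write association summary statistics as TSV
#'
#' Columns: chrom, pos, id, ea (effect allele = ALT), oa, eaf, beta, se, p
#' plus any extra columns present. Numeric values round-trip to at least 15
#' significant digits.
#'
#' @param results data.frame of per-variant statistics (an
#'   `assoc_result$results`, or any data.frame with the standard columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(results, path) {
  if (inherits(results, "assoc_result")) results <- results$results
  missing_cols <- setdiff(.sumstat_cols, names(results))
  if (length(missing_cols))
    stop("summary statistics lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  ord <- c(.sumstat_cols, setdiff(names(results), .sumstat_cols))
  data.table::fwrite(as.data.frame(results)[, ord], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read association summary statistics from TSV
#' @param path path written by [write_summary_stats()].
#' @return data.frame of per-variant statistics.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  missing_cols <- setdiff(.sumstat_cols, names(d))
  if (length(missing_cols))
    stop("summary statistics lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  d
}
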