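#' Pearson chi-square goodness-of-fit test
#'
#' `sum((O - E)^2 / E)` against expected proportions, without continuity
#' correction; p-value from the chi-square distribution with `k - 1`
#' degrees of freedom. Used for the male/female split in Table-1-style
#' descriptives.
#'
#' @param counts nonnegative observed counts.
#' @param probs expected proportions, summing to 1 (default: uniform).
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_gof <- function(counts, probs = rep(1 / length(counts), length(counts))) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-8) stop("probs must sum to 1")
  expected <- sum(counts) * probs
  if (any(expected == 0)) stop("expected count of zero")
  stat <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Without continuity correction (1 df). Cells are
#' `rbind(c(a, c), c(b, d))`: `a`/`b` are the events/non-events in group 1,
#' `c`/`d` in group 2. Identical to
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  a <- as.double(a); b <- as.double(b)
  c <- as.double(c); d <- as.double(d)
  tab <- matrix(c(a, b, c, d), nrow = 2)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  n <- sum(tab)
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided,
#' computed from group means, SDs and sizes (the form reproducible from a
#' printed descriptive table).
#'
#' @param mean1,sd1,n1 summary statistics for group 1.
#' @param mean2,sd2,n2 summary statistics for group 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Descriptive group comparison table
#'
#' Table-1-style summary by a binary grouping column: mean (SD) and Welch t
#' for continuous traits, N (%) and uncorrected chi-square for binary
#' traits, plus a goodness-of-fit test of the group split against 50/50.
#'
#' @param pheno phenotype data.frame (see [read_phenotypes()]).
#' @param group name of a 0/1 column to split on (default `"sex"`).
#' @param continuous,binary trait columns to summarize.
#' @return data.frame with one row per trait.
#' @export
table1 <- function(pheno, group = "sex",
                   continuous = c("age", "bmi", "bilirubin"),
                   binary = c("t2d", "hypertension")) {
  if (!group %in% names(pheno)) stop("grouping column '", group, "' missing")
  gidx <- pheno[[group]] == 1
  n1 <- sum(gidx); n2 <- sum(!gidx)
  rows <- list()
  split_test <- chisq_gof(c(n1, n2), c(0.5, 0.5))
  rows[["n"]] <- data.frame(trait = "n", group1 = n1, group2 = n2,
                            stat = split_test$statistic, p = split_test$p)
  for (tr in binary) {
    k1 <- sum(pheno[[tr]][gidx] == 1, na.rm = TRUE)
    k2 <- sum(pheno[[tr]][!gidx] == 1, na.rm = TRUE)
    ts <- chisq_2x2(k1, n1 - k1, k2, n2 - k2)
    rows[[tr]] <- data.frame(trait = tr, group1 = k1, group2 = k2,
                             stat = ts$statistic, p = ts$p)
  }
  for (tr in continuous) {
    x1 <- pheno[[tr]][gidx]; x2 <- pheno[[tr]][!gidx]
    ts <- welch_t_summary(mean(x1), stats::sd(x1), length(x1),
                          mean(x2), stats::sd(x2), length(x2))
    rows[[tr]] <- data.frame(trait = tr, group1 = mean(x1), group2 = mean(x2),
                             stat = ts$t, p = ts$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
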