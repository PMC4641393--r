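# Group-comparison statistics: point-biserial / Pearson correlation,
# Mann-Whitney-Wilcoxon test with an exact small-sample path, chi-squared
# comparison of TM-count histograms, and orthogroup prediction consistency.

#' Correlate per-genome TM fraction with a genome covariate
#'
#' Pearson product-moment correlation of \code{tm_fraction} against a genome
#' label: virion lipid association (binary: lipid_associated and
#' tentative_lipid code as 1), host domain (Archaea = 1, Bacteria = 0) or
#' genome size (\code{n_proteins}). For binary covariates this is the
#' point-biserial coefficient.
#'
#' @param census a \code{genome_census} table (virus genomes).
#' @param metadata metadata table.
#' @param covariate one of \code{"lipid_binary"}, \code{"host_domain_binary"},
#'   \code{"n_proteins"}.
#' @return The correlation coefficient.
#' @export
tm_correlate <- function(census, metadata,
                         covariate = c("lipid_binary", "host_domain_binary",
                                       "n_proteins")) {
  covariate <- match.arg(covariate)
  m <- merge(census, metadata, by = "genome_id")
  if (nrow(m) < 3) stop("need at least 3 genomes to correlate")
  x <- switch(covariate,
              lipid_binary = as.numeric(m$lipid_class %in%
                                          c("lipid_associated",
                                            "tentative_lipid")),
              host_domain_binary = as.numeric(m$host_domain == "Archaea"),
              n_proteins = m$n_proteins)
  if (stats::sd(x) == 0 || stats::sd(m$tm_fraction) == 0)
    stop("undefined correlation: zero variance in ",
         if (stats::sd(x) == 0) covariate else "tm_fraction")
  stats::cor(m$tm_fraction, x)
}

# Exact two-sided MWW p by full enumeration of all C(n+m, n) group labelings
# of the midrank vector; handles ties. Two-sided convention: probability of a
# U at least as far from nm/2 as observed.
mww_enumerate <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  combos <- utils::combn(n + m, n)
  u_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mean(abs(u_all - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-9)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided test of distributional shift between two samples. Small samples
#' are handled exactly: untied samples through the exact null distribution of
#' the U statistic, tied samples by full enumeration of all group labelings of
#' the midranks (feasible for the sample sizes where ties matter here). Larger
#' samples use the normal approximation with the tie-corrected variance and a
#' continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_limit use an exact path when \code{length(x)*length(y)} is at
#'   most this (untied data), or when the number of labelings
#'   \code{choose(n+m, n)} is at most 200000 (tied data).
#' @return List of class \code{mww_test} with \code{u} (U statistic for the
#'   first sample), \code{p_value}, \code{method}.
#' @export
#' @examples
#' mww_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
mww_test <- function(x, y, exact_limit = 400) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n * m <= exact_limit) {
    p <- if (u > n * m / 2) 2 * stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    else 2 * stats::pwilcox(u, n, m)
    p <- min(1, p)
    method <- "exact"
  } else if (ties && choose(n + m, n) <= 2e5) {
    p <- mww_enumerate(x, y)
    method <- "exact_enumeration"
  } else {
    tie_tab <- table(r)
    sigma2 <- n * m / 12 *
      (n + m + 1 - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
    z <- (abs(u - n * m / 2) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(1, p)
    method <- "normal_approximation"
  }
  structure(list(u = u, p_value = p, method = method, n = n, m = m),
            class = "mww_test")
}

#' @export
print.mww_test <- function(x, ...) {
  p <- if (x$p_value < 2e-16) "< 2e-16" else format(x$p_value, digits = 4)
  cat(sprintf("Mann-Whitney-Wilcoxon test (%s): U = %g (n = %d, m = %d), two-sided p %s%s\n",
              x$method, x$u, x$n, x$m,
              if (x$p_value < 2e-16) "" else "= ", p))
  invisible(x)
}

# Merge histogram bins rightward until every pooled expected count is >= 5.
# obs is a 2 x K matrix; returns the merged matrix.
merge_low_expected <- function(obs, min_expected = 5) {
  repeat {
    if (ncol(obs) <= 2) return(obs)
    expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    bad <- which(expected < min_expected, arr.ind = TRUE)
    if (nrow(bad) == 0) return(obs)
    j <- max(bad[, 2])
    target <- if (j == ncol(obs)) j - 1 else j + 1
    obs[, target] <- obs[, target] + obs[, j]
    keep <- setdiff(seq_len(ncol(obs)), j)
    obs <- obs[, keep, drop = FALSE]
  }
}

#' Chi-squared comparison of two TM-count histograms
#'
#' Pearson chi-squared test of homogeneity between two count distributions
#' (e.g. pooled virus vs host TM-segment-count histograms). Bins whose
#' expected count under the margins falls below 5 are merged into their
#' right neighbor (the rightmost bin merges leftward) before the statistic is
#' computed; no continuity correction.
#'
#' @param a,b named integer vectors over the same bins (names aligned by
#'   union; absent bins count 0), or a 2-row matrix given as \code{a} alone.
#' @return List of class \code{chisq_hist_test}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{n_bins_used}.
#' @export
chisq_hist_test <- function(a, b = NULL) {
  if (is.null(b)) {
    obs <- as.matrix(a)
    if (nrow(obs) != 2) stop("expected a 2-row table")
  } else {
    bins <- union(names(a), names(b))
    if (is.null(bins)) {
      stopifnot(length(a) == length(b))
      obs <- rbind(a, b)
    } else {
      av <- stats::setNames(rep(0, length(bins)), bins); av[names(a)] <- a
      bv <- stats::setNames(rep(0, length(bins)), bins); bv[names(b)] <- b
      obs <- rbind(av, bv)
    }
  }
  obs <- obs[, colSums(obs) > 0, drop = FALSE]
  obs <- merge_low_expected(obs)
  if (ncol(obs) < 2) stop("fewer than 2 usable bins after merging")
  ct <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, n_bins_used = ncol(obs)),
            class = "chisq_hist_test")
}

#' @export
print.chisq_hist_test <- function(x, ...) {
  p <- if (x$p_value < 1e-300) "< 1e-300" else format(x$p_value, digits = 4)
  cat(sprintf("Chi-squared homogeneity test: X^2 = %.4g, df = %d (%d bins), p %s%s\n",
              x$statistic, x$df, x$n_bins_used,
              if (x$p_value < 1e-300) "" else "= ", p))
  invisible(x)
}

#' Consistency of TM predictions within orthogroups
#'
#' Orthologous proteins should receive the same TM-segment count; this
#' measures how often they do. For every orthogroup with at least two
#' predicted members, the member TM counts are collected, uniformity is exact
#' count equality across members, and the discordance magnitude is the
#' difference between the largest and smallest member count.
#'
#' @param predictions a \code{tm_topology_set}.
#' @param orthogroups membership table.
#' @return List of class \code{consistency_report}: \code{per_group}
#'   data.frame (\code{group_id}, \code{n_members}, \code{is_uniform},
#'   \code{max_diff}, \code{counts} as a list-column) and aggregates
#'   \code{fraction_uniform}, \code{frac_discordant_by1},
#'   \code{frac_discordant_by2}, \code{frac_discordant_gt2}.
#' @export
orthogroup_consistency <- function(predictions, orthogroups) {
  n_tm_by_id <- stats::setNames(predictions$n_tm, predictions$protein_id)
  og <- orthogroups[orthogroups$protein_id %in% predictions$protein_id, ]
  groups <- split(og$protein_id, og$group_id)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0)
    stop("no orthogroup with at least 2 predicted members")
  per <- data.frame(group_id = names(groups),
                    n_members = lengths(groups),
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- lapply(groups, function(ids) unname(n_tm_by_id[ids]))
  per$max_diff <- vapply(counts, function(k) max(k) - min(k), 0L)
  per$is_uniform <- per$max_diff == 0
  per$counts <- I(counts)
  disc <- per$max_diff[!per$is_uniform]
  structure(list(
    per_group = per,
    fraction_uniform = mean(per$is_uniform),
    frac_discordant_by1 = if (length(disc)) mean(disc == 1) else NA_real_,
    frac_discordant_by2 = if (length(disc)) mean(disc == 2) else NA_real_,
    frac_discordant_gt2 = if (length(disc)) mean(disc > 2) else NA_real_),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Orthogroup consistency over %d group(s): %.1f%% uniform\n",
              nrow(x$per_group), 100 * x$fraction_uniform))
  if (!is.na(x$frac_discordant_by1))
    cat(sprintf("  of discordant groups: %.1f%% differ by 1 segment, %.1f%% by 2, %.1f%% by >2\n",
                100 * x$frac_discordant_by1, 100 * x$frac_discordant_by2,
                100 * x$frac_discordant_gt2))
  invisible(x)
}
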