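# Cross-predictor concordance and TM-segment length statistics.

#' Concordance between two topology prediction sets
#'
#' Compares per-protein TM-segment counts between two predictors (e.g. the
#' built-in caller vs parsed Phobius output) over the shared protein-id
#' universe. Reports the fraction of proteins with identical counts and, among
#' the discordant ones, the fractions differing by exactly 1, exactly 2, and
#' more than 2 segments.
#'
#' @param a,b \code{tm_topology_set} objects.
#' @return List of class \code{concordance_summary}: \code{n_common},
#'   \code{frac_identical}, \code{frac_diff1}, \code{frac_diff2},
#'   \code{frac_diff_gt2} (the latter three over discordant proteins;
#'   \code{NA} when none).
#' @export
compare_predictions <- function(a, b) {
  common <- intersect(a$protein_id, b$protein_id)
  if (length(common) == 0) stop("no shared protein ids between the two sets")
  dropped <- length(union(a$protein_id, b$protein_id)) - length(common)
  if (dropped > 0)
    message(dropped, " protein(s) present in only one set ignored")
  ka <- stats::setNames(a$n_tm, a$protein_id)[common]
  kb <- stats::setNames(b$n_tm, b$protein_id)[common]
  d <- abs(ka - kb)
  disc <- d[d > 0]
  structure(list(n_common = length(common),
                 frac_identical = mean(d == 0),
                 frac_diff1 = if (length(disc)) mean(disc == 1) else NA_real_,
                 frac_diff2 = if (length(disc)) mean(disc == 2) else NA_real_,
                 frac_diff_gt2 = if (length(disc)) mean(disc > 2) else NA_real_),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Prediction concordance over %d shared protein(s): %.1f%% identical TM counts\n",
              x$n_common, 100 * x$frac_identical))
  if (!is.na(x$frac_diff1))
    cat(sprintf("  of discordant: %.1f%% differ by 1, %.1f%% by 2, %.1f%% by >2\n",
                100 * x$frac_diff1, 100 * x$frac_diff2,
                100 * x$frac_diff_gt2))
  invisible(x)
}

#' TM-segment length statistics
#'
#' Lengths (end - start + 1, aa) of every predicted segment across a topology
#' set, with a per-residue histogram. Membrane-spanning helices cluster near
#' 20 aa.
#'
#' @param predictions a \code{tm_topology_set}.
#' @return List with \code{n_segments}, \code{mean}, \code{median},
#'   \code{histogram} (named counts per length).
#' @export
segment_length_stats <- function(predictions) {
  lens <- unlist(lapply(predictions$segments, function(s)
    if (nrow(s) > 0) s[, "end"] - s[, "start"] + 1 else integer(0)))
  if (length(lens) == 0) stop("no TM segments in the prediction set")
  h <- table(factor(lens, levels = seq(min(lens), max(lens))))
  list(n_segments = length(lens), mean = mean(lens),
       median = stats::median(lens),
       histogram = stats::setNames(as.integer(h), names(h)))
}
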