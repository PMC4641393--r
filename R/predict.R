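# Built-in alpha-helical TM topology predictor: hydropathy segment calling,
# positive-inside orientation, and an N-terminal signal-peptide guard.

#' Predictor configuration
#'
#' Parameters of the sliding-window TM segment caller. Defaults were chosen so
#' that membrane helices of typical length (~21 aa) and composition are called
#' as single segments while soluble sequence is left alone.
#'
#' @param window sliding-window width in residues over which hydropathy is
#'   averaged. 19 residues is the classic choice for a membrane-spanning helix.
#' @param threshold minimum mean window hydropathy (scale units) for a window
#'   to seed a segment.
#' @param min_len minimum accepted segment length (aa); shorter calls are
#'   discarded.
#' @param max_len maximum accepted segment length (aa); longer merged runs are
#'   split at their least hydrophobic interior residue.
#' @param merge_gap adjacent covered runs separated by fewer than this many
#'   residues are merged before length filtering.
#' @param trim_cutoff after merging, run ends are trimmed inward past residues
#'   whose hydropathy is below this value, so a call tracks the hydrophobic
#'   core rather than the full extent of every qualifying window.
#' @param scale a \code{\link{hydropathy_scale}}.
#' @param sp_max_start last residue index at which a signal-peptide
#'   hydrophobic core may begin.
#' @param sp_h_min,sp_h_max length bounds (aa) of the signal-peptide
#'   hydrophobic core.
#' @param sp_h_cutoff per-residue hydropathy above which a residue counts as
#'   part of the signal hydrophobic core.
#' @return A list of class \code{tm_predictor_config}.
#' @export
predictor_config <- function(window = 19, threshold = 1.6,
                             min_len = 15, max_len = 35, merge_gap = 3,
                             trim_cutoff = 0, scale = hydropathy_scale(),
                             sp_max_start = 10, sp_h_min = 7, sp_h_max = 15,
                             sp_h_cutoff = 1.5) {
  stopifnot(window >= 5, min_len >= 1, max_len >= min_len, merge_gap >= 0)
  structure(list(window = window, threshold = threshold, min_len = min_len,
                 max_len = max_len, merge_gap = merge_gap,
                 trim_cutoff = trim_cutoff, scale = scale,
                 sp_max_start = sp_max_start, sp_h_min = sp_h_min,
                 sp_h_max = sp_h_max, sp_h_cutoff = sp_h_cutoff),
            class = "tm_predictor_config")
}

# Runs of TRUE in a logical vector -> matrix with columns start, end.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# Split a run [s, e] recursively at its least hydrophobic interior residue
# until every piece is <= max_len. Interior excludes the two end residues so
# a split always shrinks both pieces. The split residue itself is dropped.
split_long_run <- function(s, e, h, max_len) {
  if (e - s + 1 <= max_len) return(list(c(s, e)))
  interior <- (s + 1):(e - 1)
  p <- interior[which.min(h[interior])]
  c(split_long_run(s, p - 1, h, max_len), split_long_run(p + 1, e, h, max_len))
}

# Core segment caller on a per-residue hydropathy vector. Returns a matrix
# with columns start, end (1-based inclusive), possibly 0 rows.
call_segments <- function(h, config) {
  n <- length(h)
  empty <- cbind(start = integer(0), end = integer(0))
  wm <- window_means(h, config$window)
  if (length(wm) == 0) return(empty)
  covered <- rep(FALSE, n)
  # small epsilon so window sums landing exactly on the threshold are kept
  # regardless of accumulation order
  for (s in which(wm >= config$threshold - 1e-9))
    covered[s:(s + config$window - 1)] <- TRUE
  if (!any(covered)) return(empty)
  runs <- logical_runs(covered)
  # merge runs separated by gap < merge_gap
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[i, "start"] - last[2] - 1 < config$merge_gap)
        keep[[length(keep)]] <- c(last[1], runs[i, "end"])
      else keep[[length(keep) + 1]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
    colnames(runs) <- c("start", "end")
  }
  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, 1]; e <- runs[i, 2]
    while (s <= e && h[s] < config$trim_cutoff) s <- s + 1
    while (e >= s && h[e] < config$trim_cutoff) e <- e - 1
    if (s > e) next
    out <- c(out, split_long_run(s, e, h, config$max_len))
  }
  if (length(out) == 0) return(empty)
  segs <- do.call(rbind, out)
  segs <- segs[segs[, 2] - segs[, 1] + 1 >= config$min_len, , drop = FALSE]
  colnames(segs) <- c("start", "end")
  segs[order(segs[, 1]), , drop = FALSE]
}

#' Detect an N-terminal signal peptide
#'
#' Heuristic recognizer of the tripartite signal-peptide architecture: a short
#' positively charged n-region (at least one Lys/Arg in the first five
#' residues), a hydrophobic h-region of 7-15 residues starting within the
#' first \code{sp_max_start} residues, and a c-region containing small
#' residues (Ala/Gly/Ser) just downstream of the h-region, all within the
#' N-terminal 30 residues.
#'
#' @param sequence amino-acid string (sanitized).
#' @param config a \code{\link{predictor_config}}.
#' @return List with \code{signal} (logical) and \code{cleavage_end} (last
#'   residue of the predicted signal region, \code{NA} when no signal).
#' @export
detect_signal_peptide <- function(sequence, config = predictor_config()) {
  n <- nchar(sequence)
  none <- list(signal = FALSE, cleavage_end = NA_integer_)
  if (n < 25) return(none)
  res <- strsplit(substr(sequence, 1, min(n, 30)), "")[[1]]
  if (!any(res[1:5] %in% c("K", "R"))) return(none)
  h <- unname(config$scale$values[res])
  hydro <- !is.na(h) & h >= config$sp_h_cutoff
  runs <- logical_runs(hydro)
  if (nrow(runs) == 0) return(none)
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, 1]; len <- runs[i, 2] - s + 1
    if (s > config$sp_max_start || len < config$sp_h_min) next
    e <- s + min(len, config$sp_h_max) - 1
    # c-region: a small residue within 6 residues after the h-region
    cr <- (e + 1):min(length(res), e + 6)
    if (length(cr) > 0 && any(res[cr] %in% c("A", "G", "S"))) {
      cleave <- cr[which(res[cr] %in% c("A", "G", "S"))]
      return(list(signal = TRUE, cleavage_end = max(cleave)))
    }
  }
  none
}

#' Orient a topology by the positive-inside rule
#'
#' Lys/Arg residues are enriched on the cytoplasmic side of membrane proteins.
#' Inter-segment loops alternate sides; this counts Lys+Arg over the loops
#' assigned 'in' under each of the two possible orientations and returns the
#' orientation of the N-terminal side that places more Lys+Arg inside. Ties
#' resolve to 'in', the topology class strongly preferred across organisms.
#'
#' @param segments matrix with columns start, end (1-based inclusive),
#'   ascending and non-overlapping; at least one row.
#' @param sequence the protein sequence the segments index into.
#' @param flank only loop residues within this many positions of an adjacent
#'   TM segment are counted; the positive-inside enrichment is a property of
#'   the membrane-proximal part of a loop, and counting whole loops would let
#'   a long soluble tail swamp the signal.
#' @return \code{"in"} or \code{"out"} for the N-terminal side.
#' @export
decide_orientation <- function(segments, sequence, flank = 15) {
  stopifnot(nrow(segments) >= 1)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  k <- nrow(segments)
  bounds <- rbind(c(0, segments[1, 1] - 1),
                  if (k > 1) cbind(segments[-k, 2], segments[-1, 1] - 1),
                  c(segments[k, 2], n + 1))
  kr <- vapply(seq_len(nrow(bounds)), function(i) {
    s <- bounds[i, 1] + 1; e <- min(bounds[i, 2], n)
    if (s > e) return(0L)
    # membrane-proximal window(s): last `flank` residues before a following
    # segment, first `flank` after a preceding one
    keep <- rep(FALSE, e - s + 1)
    if (i > 1) keep[seq_len(min(flank, e - s + 1))] <- TRUE
    if (i < nrow(bounds))
      keep[seq(to = e - s + 1, length.out = min(flank, e - s + 1))] <- TRUE
    sum(res[s:e][keep] %in% c("K", "R"))
  }, integer(1))
  loop_idx <- seq_len(nrow(bounds)) - 1  # 0 = N-terminal loop
  in_if_nin <- sum(kr[loop_idx %% 2 == 0])
  in_if_nout <- sum(kr[loop_idx %% 2 == 1])
  if (in_if_nout > in_if_nin) "out" else "in"
}

#' Predict the TM topology of one protein
#'
#' Sliding-window hydropathy segment caller with positive-inside orientation
#' and a signal-peptide guard. Windows whose mean hydropathy reaches
#' \code{threshold} seed candidate regions; overlapping or nearly adjacent
#' regions are merged, trimmed to their hydrophobic core, split if longer than
#' \code{max_len}, and discarded if shorter than \code{min_len}. When a signal
#' peptide is detected, any segment lying wholly within the signal region is
#' removed (its hydrophobic core is an export signal, not a membrane anchor).
#'
#' @param protein either an amino-acid string or a one-row entry from
#'   \code{\link{read_proteomes}} (a list with \code{sequence} and
#'   \code{protein_id}).
#' @param config a \code{\link{predictor_config}}.
#' @param protein_id identifier recorded in the result when \code{protein} is
#'   a bare string.
#' @return Object of class \code{tm_topology}: list with \code{protein_id},
#'   \code{segments} (matrix start/end, 1-based inclusive), \code{n_tm},
#'   \code{n_terminal_side}, \code{signal_peptide}, \code{source}.
#' @export
#' @examples
#' p <- paste0(strrep("K", 8), strrep("L", 21), strrep("K", 8))
#' predict_topology(p)
predict_topology <- function(protein, config = predictor_config(),
                             protein_id = "protein") {
  if (is.list(protein)) {
    sequence <- protein$sequence
    protein_id <- protein$protein_id
  } else sequence <- protein
  h <- residue_hydropathy(sequence, config$scale)
  segs <- call_segments(h, config)
  sp <- detect_signal_peptide(sequence, config)
  if (sp$signal && nrow(segs) > 0)
    segs <- segs[segs[, "end"] > sp$cleavage_end, , drop = FALSE]
  side <- if (nrow(segs) > 0) decide_orientation(segs, sequence) else "in"
  structure(list(protein_id = protein_id, segments = segs,
                 n_tm = nrow(segs), n_terminal_side = side,
                 signal_peptide = sp$signal, source = "builtin"),
            class = "tm_topology")
}

#' @export
print.tm_topology <- function(x, ...) {
  cat("TM topology prediction (", x$source, ") for ", x$protein_id, "\n",
      sep = "")
  cat("  segments:", x$n_tm,
      if (x$n_tm > 0) paste0("[", paste(x$segments[, 1], x$segments[, 2],
                                        sep = "-", collapse = ", "), "]"),
      "\n")
  cat("  N-terminal side:", x$n_terminal_side,
      " signal peptide:", x$signal_peptide, "\n")
  invisible(x)
}

#' Predict topology for a whole protein set
#'
#' @param proteins a protein table as returned by \code{\link{read_proteomes}}
#'   (data.frame with \code{protein_id}, \code{genome_id}, \code{sequence}).
#' @param config a \code{\link{predictor_config}}.
#' @return A topology set: data.frame of class \code{tm_topology_set} with
#'   columns \code{protein_id}, \code{genome_id}, \code{n_tm},
#'   \code{n_terminal_side}, \code{signal_peptide}, \code{source}, and a
#'   list-column \code{segments} of start/end matrices.
#' @export
predict_proteome <- function(proteins, config = predictor_config()) {
  preds <- lapply(seq_len(nrow(proteins)), function(i)
    predict_topology(proteins$sequence[i], config, proteins$protein_id[i]))
  topology_set(preds, genome_id = proteins$genome_id)
}

# Assemble a list of tm_topology objects into a tm_topology_set data.frame.
topology_set <- function(preds, genome_id = NA_character_) {
  df <- data.frame(
    protein_id = vapply(preds, `[[`, "", "protein_id"),
    genome_id = genome_id,
    n_tm = vapply(preds, `[[`, 0L, "n_tm"),
    n_terminal_side = vapply(preds, `[[`, "", "n_terminal_side"),
    signal_peptide = vapply(preds, `[[`, TRUE, "signal_peptide"),
    source = vapply(preds, `[[`, "", "source"),
    stringsAsFactors = FALSE)
  df$segments <- I(lapply(preds, `[[`, "segments"))
  class(df) <- c("tm_topology_set", "data.frame")
  df
}

#' @export
print.tm_topology_set <- function(x, ...) {
  cat("TM topology set:", nrow(x), "proteins,",
      sum(x$n_tm > 0), "with >=1 TM segment\n")
  cat("sources:", paste(unique(x$source), collapse = ", "), "\n")
  invisible(x)
}
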