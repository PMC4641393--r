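# Per-genome and cross-genome census statistics: TM counts and fractions,
# TM-segment-count histograms, conservation cross-tabulations, protein-length
# stratification, and representative-genome selection.

# Histogram of TM counts with an overflow bucket at `cap`+. Names are
# "0".."cap" plus "cap+".
tm_count_histogram <- function(n_tm, cap = 15) {
  labels <- c(as.character(0:cap), paste0(cap, "+"))
  binned <- ifelse(n_tm > cap, paste0(cap, "+"), as.character(n_tm))
  h <- table(factor(binned, levels = labels))
  stats::setNames(as.integer(h), labels)
}

#' Census one or more genomes
#'
#' Aggregates per-genome TM statistics from a protein table, its topology
#' predictions and (optionally) an orthogroup membership table: protein
#' counts, number and fraction of TM proteins (those with at least one TM
#' segment, signal peptide or not), a TM-segment-count histogram with an
#' overflow bucket, and a 2x2 TM-by-conserved cross-tabulation.
#'
#' @param proteins protein table (\code{\link{read_proteomes}}).
#' @param predictions a \code{tm_topology_set} covering every protein.
#' @param orthogroups optional data.frame with \code{protein_id},
#'   \code{group_id}; proteins present there count as conserved.
#' @param cap histogram overflow cap; counts above it pool into the
#'   \code{cap+} bucket.
#' @return A data.frame of class \code{genome_census}, one row per genome,
#'   with columns \code{genome_id}, \code{n_proteins}, \code{n_tm},
#'   \code{tm_fraction}, \code{n_in_orthogroups}, the four cross-tab cells
#'   (\code{tm_conserved}, \code{tm_not_conserved}, \code{non_tm_conserved},
#'   \code{non_tm_not_conserved}) and a list-column \code{histogram}.
#' @export
genome_census <- function(proteins, predictions, orthogroups = NULL,
                          cap = 15) {
  missing <- setdiff(proteins$protein_id, predictions$protein_id)
  if (length(missing) > 0)
    stop("prediction missing for protein(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  n_tm_by_id <- stats::setNames(predictions$n_tm, predictions$protein_id)
  conserved_ids <- if (is.null(orthogroups)) character(0) else
    orthogroups$protein_id
  rows <- lapply(split(proteins, proteins$genome_id), function(p) {
    k <- unname(n_tm_by_id[p$protein_id])
    tm <- k >= 1
    cons <- p$protein_id %in% conserved_ids
    data.frame(genome_id = p$genome_id[1],
               n_proteins = nrow(p),
               n_tm = sum(tm),
               tm_fraction = sum(tm) / nrow(p),
               n_in_orthogroups = sum(cons),
               tm_conserved = sum(tm & cons),
               tm_not_conserved = sum(tm & !cons),
               non_tm_conserved = sum(!tm & cons),
               non_tm_not_conserved = sum(!tm & !cons),
               stringsAsFactors = FALSE)
  })
  census <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  census$histogram <- I(lapply(split(proteins, proteins$genome_id),
                               function(p)
                                 tm_count_histogram(
                                   unname(n_tm_by_id[p$protein_id]), cap)))
  class(census) <- c("genome_census", "data.frame")
  census
}

#' @export
print.genome_census <- function(x, ...) {
  cat("Genome census:", nrow(x), "genome(s)\n")
  cat(sprintf("  total proteins %d, TM proteins %d (mean per-genome fraction %.3f)\n",
              sum(x$n_proteins), sum(x$n_tm), mean(x$tm_fraction)))
  invisible(x)
}

#' @export
summary.genome_census <- function(object, ...) {
  cat("Genome census over", nrow(object), "genome(s)\n")
  print(summary(object$tm_fraction))
  pooled <- aggregate_histogram(object, normalize = TRUE)
  cat("Pooled TM-count distribution (head):\n")
  print(round(utils::head(pooled, 8), 4))
  invisible(object)
}

#' Pool TM-segment-count histograms over genomes
#'
#' @param census a \code{genome_census} table.
#' @param normalize when TRUE return proportions summing to 1 over proteins.
#' @return Named numeric vector over TM-count bins.
#' @export
aggregate_histogram <- function(census, normalize = FALSE) {
  stopifnot(nrow(census) >= 1)
  pooled <- Reduce(`+`, census$histogram)
  if (normalize) pooled / sum(pooled) else pooled
}

#' Stratify proteins by length and TM-segment class
#'
#' Bins proteins into half-open length intervals [lo, hi) of width
#' \code{bin_width} and, within each bin, counts proteins by TM-segment
#' class 0, 1, 2, 3 and 4+ — the stratification used to show that the scarcity
#' of polytopic proteins in viruses is not a protein-length artifact.
#'
#' @param proteins protein table with \code{length}.
#' @param predictions matching \code{tm_topology_set}.
#' @param bin_width bin width in amino acids (>= 10).
#' @return data.frame with \code{bin_lo}, \code{bin_hi}, per-class counts
#'   \code{tm0}..\code{tm3}, \code{tm4plus}, and \code{total}.
#' @export
stratify_by_length <- function(proteins, predictions, bin_width = 100) {
  stopifnot(bin_width >= 10)
  n_tm_by_id <- stats::setNames(predictions$n_tm, predictions$protein_id)
  k <- unname(n_tm_by_id[proteins$protein_id])
  if (anyNA(k)) stop("prediction missing for some proteins")
  cls <- pmin(k, 4L)
  lo <- (proteins$length %/% bin_width) * bin_width
  tab <- table(factor(lo, levels = sort(unique(lo))),
               factor(cls, levels = 0:4))
  out <- data.frame(bin_lo = as.integer(rownames(tab)),
                    bin_hi = as.integer(rownames(tab)) + bin_width,
                    tm0 = as.integer(tab[, "0"]),
                    tm1 = as.integer(tab[, "1"]),
                    tm2 = as.integer(tab[, "2"]),
                    tm3 = as.integer(tab[, "3"]),
                    tm4plus = as.integer(tab[, "4"]))
  out$total <- out$tm0 + out$tm1 + out$tm2 + out$tm3 + out$tm4plus
  out
}

# Orthogroup sets per genome: named list genome_id -> character vector of
# group ids (one entry per orthogroup-assigned gene; duplicates kept so gene
# counts reflect genes, not distinct groups).
genome_group_sets <- function(proteins, orthogroups) {
  m <- merge(proteins[, c("protein_id", "genome_id")], orthogroups,
             by = "protein_id")
  split(m$group_id, factor(m$genome_id, levels = unique(proteins$genome_id)))
}

#' Select representative virus genomes by shared-gene clustering
#'
#' Groups of genomes that share at least \code{threshold} of their genes are
#' collapsed to one randomly chosen representative. The shared fraction of a
#' genome pair is the number of orthogroups they have in common divided by
#' the orthogroup-assigned gene count of the smaller genome; pairs at or
#' above the threshold are linked and single-linkage connected components
#' form the redundancy groups. Genomes with no orthogroup-assigned genes
#' cannot be compared and are kept unconditionally with a warning.
#'
#' @param proteins protein table.
#' @param orthogroups orthogroup membership table.
#' @param threshold shared-gene fraction in (0, 1].
#' @param seed integer seed for the random representative choice.
#' @param method \code{"min"} (default; denominator = smaller genome's
#'   assigned gene count) or \code{"jaccard"}.
#' @return Character vector of retained genome ids.
#' @export
select_representatives <- function(proteins, orthogroups, threshold = 0.9,
                                   seed = 1, method = c("min", "jaccard")) {
  stopifnot(threshold > 0, threshold <= 1)
  method <- match.arg(method)
  genomes <- unique(proteins$genome_id)
  sets <- genome_group_sets(proteins, orthogroups)
  sizes <- lengths(sets)
  zero <- genomes[sizes[genomes] == 0 | is.na(sizes[genomes])]
  if (length(zero) > 0)
    warning("genome(s) with no orthogroup-assigned genes kept ",
            "unconditionally: ", paste(zero, collapse = ", "))
  comp <- setdiff(genomes, zero)
  if (length(comp) < 2) return(genomes)
  usets <- lapply(sets[comp], unique)
  edges <- character(0)
  for (i in seq_len(length(comp) - 1)) for (j in (i + 1):length(comp)) {
    shared <- length(intersect(usets[[i]], usets[[j]]))
    denom <- switch(method,
                    min = min(sizes[comp[i]], sizes[comp[j]]),
                    jaccard = length(union(usets[[i]], usets[[j]])))
    if (shared / denom >= threshold) edges <- c(edges, comp[i], comp[j])
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(comp)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  membership <- igraph::components(g)$membership
  reps <- with_seed(seed, vapply(split(comp, membership[comp]),
                                 function(ids) sample(ids, 1), ""))
  sort(c(unname(reps), zero))
}

#' Select one cellular representative per genus
#'
#' Keeps, within each genus, the genome encoding the most proteins (largest
#' genome); ties resolve to the lexicographically smallest genome id. Genomes
#' with no genus recorded are kept with a warning.
#'
#' @param census a \code{genome_census} table for the cellular genomes
#'   (\code{n_proteins} is the size criterion).
#' @param metadata metadata table with \code{genome_id} and \code{genus}.
#' @return Character vector of retained genome ids.
#' @export
select_cellular_representatives <- function(census, metadata) {
  m <- merge(census[, c("genome_id", "n_proteins")],
             metadata[, c("genome_id", "genus")], by = "genome_id")
  nogenus <- is.na(m$genus) | m$genus == "" | m$genus == "none"
  if (any(nogenus))
    warning("genome(s) without genus kept unconditionally: ",
            paste(m$genome_id[nogenus], collapse = ", "))
  kept <- vapply(split(m[!nogenus, ], m$genus[!nogenus]), function(d) {
    d <- d[order(-d$n_proteins, d$genome_id), ]
    d$genome_id[1]
  }, "")
  sort(c(unname(kept), m$genome_id[nogenus]))
}
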