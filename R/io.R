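# Readers and writers for the external formats the census touches: protein
# FASTA, Phobius short-format topology output, and the plain TSV tables
# (genome metadata, orthogroups, prophage regions, census output).

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Sanitize an amino-acid sequence
#'
#' Removes every character that is not one of the 20 standard one-letter
#' residue codes: ambiguity codes (B, J, O, U, X, Z), stop symbols
#' (\code{*}) and gap characters are deleted, not substituted. Lower-case
#' input is upper-cased first. Idempotent.
#'
#' @param sequence character vector of amino-acid strings.
#' @return Character vector of sanitized sequences (possibly empty strings).
#' @export
sanitize_sequence <- function(sequence) {
  gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", toupper(sequence))
}

#' Read per-genome protein FASTA files
#'
#' Each file holds one genome's proteins. The genome id is taken from the
#' \code{genome_ids} sidecar mapping when supplied; otherwise from the part of
#' the FASTA header before the first \code{|} when present, else from the file
#' name (without extension). The protein id is the remainder of the first
#' header word. Sequences are sanitized with \code{\link{sanitize_sequence}};
#' records that are empty after sanitization are dropped with a warning.
#'
#' @param paths FASTA file paths.
#' @param genome_ids optional character vector, one genome id per path.
#' @return Protein table: data.frame with columns \code{protein_id},
#'   \code{genome_id}, \code{sequence}, \code{length}.
#' @export
read_proteomes <- function(paths, genome_ids = NULL) {
  if (!is.null(genome_ids)) stopifnot(length(genome_ids) == length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    path <- paths[i]
    if (!file.exists(path)) stop("cannot read FASTA file: ", path)
    aa <- Biostrings::readAAStringSet(path)
    headers <- sub("\\s.*$", "", names(aa))
    if (!is.null(genome_ids)) {
      gid <- rep(genome_ids[i], length(aa))
      pid <- headers
    } else if (all(grepl("\\|", headers)) && length(aa) > 0) {
      gid <- sub("\\|.*$", "", headers)
      pid <- sub("^[^|]*\\|", "", headers)
    } else {
      gid <- rep(sub("\\.[^.]*$", "", basename(path)), length(aa))
      pid <- headers
    }
    seqs <- sanitize_sequence(as.character(aa))
    empty <- nchar(seqs) == 0
    if (any(empty)) {
      warning(sum(empty), " record(s) in ", basename(path),
              " empty after sanitization; dropped: ",
              paste(pid[empty], collapse = ", "))
      gid <- gid[!empty]; pid <- pid[!empty]; seqs <- seqs[!empty]
    }
    if (anyDuplicated(paste(gid, pid)))
      stop("duplicate protein_id within a genome in ", path, ": ",
           paste(unique(pid[duplicated(paste(gid, pid))]), collapse = ", "))
    out[[i]] <- data.frame(protein_id = pid, genome_id = gid,
                           sequence = seqs, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(protein_id = character(0), genome_id = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  res$length <- nchar(res$sequence)
  res
}

# Parse one Phobius topology string like "i12-33o45-66i" (optionally with a
# signal-peptide part "n4-12c20/21o...") into a start/end matrix.
parse_topology_string <- function(topo) {
  body <- sub("^n[0-9]+-[0-9]+c[0-9]+/[0-9]+", "", topo)
  if (!grepl("^[io]([0-9]+-[0-9]+[io])*$", body)) return(NULL)
  m <- gregexpr("[0-9]+-[0-9]+", body)[[1]]
  if (m[1] == -1) return(cbind(start = integer(0), end = integer(0)))
  parts <- regmatches(body, gregexpr("[0-9]+-[0-9]+", body))[[1]]
  se <- t(vapply(strsplit(parts, "-"), as.integer, integer(2)))
  colnames(se) <- c("start", "end")
  se
}

#' Parse Phobius short-format output
#'
#' Reads the four-column short output of the Phobius topology predictor
#' (sequence id, number of TM segments, signal-peptide flag Y/N or 0/Y, and a
#' compact topology string such as \code{i12-33o45-66i}). Segment coordinates
#' are kept 1-based inclusive, as printed.
#'
#' @param path file path. A header line starting with \code{SEQ} is skipped.
#' @return A \code{tm_topology_set} data.frame with \code{source = "phobius"}.
#' @export
parse_phobius <- function(path) {
  if (!file.exists(path)) stop("cannot read Phobius output: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(SEQ|#)", lines)]
  preds <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 4 || is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed Phobius row at line ", i, ": ", lines[i])
    n_tm <- as.integer(f[2])
    signal <- f[3] %in% c("Y", "y")
    segs <- parse_topology_string(f[4])
    if (is.null(segs))
      stop("malformed topology string at line ", i, ": ", f[4])
    if (nrow(segs) != n_tm)
      stop("TM count ", n_tm, " disagrees with topology string at line ", i,
           ": ", f[4])
    side <- if (substr(sub("^n[0-9]+-[0-9]+c[0-9]+/[0-9]+", "", f[4]), 1, 1)
                == "o") "out" else "in"
    preds[[i]] <- structure(
      list(protein_id = f[1], segments = segs, n_tm = n_tm,
           n_terminal_side = side, signal_peptide = signal,
           source = "phobius"),
      class = "tm_topology")
  }
  topology_set(preds)
}

#' Write a topology set as Phobius-style short output
#'
#' @param predictions a \code{tm_topology_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  rows <- vapply(seq_len(nrow(predictions)), function(i) {
    segs <- predictions$segments[[i]]
    side0 <- if (predictions$n_terminal_side[i] == "out") "o" else "i"
    topo <- side0
    side <- side0
    if (nrow(segs) > 0) for (j in seq_len(nrow(segs))) {
      side <- if (side == "i") "o" else "i"
      topo <- paste0(topo, segs[j, 1], "-", segs[j, 2], side)
    }
    paste(predictions$protein_id[i], predictions$n_tm[i],
          if (predictions$signal_peptide[i]) "Y" else "N", topo,
          sep = "\t")
  }, "")
  writeLines(c("SEQID\tTM\tSP\tPREDICTION", rows), path)
  invisible(path)
}

read_required_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop("cannot read ", what, " table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(what, " table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a genome metadata table
#'
#' Plain TSV with required columns \code{genome_id}, \code{name},
#' \code{entity_class} (virus / bacterium / archaeon), \code{virus_family},
#' \code{host_domain} (Bacteria / Archaea / none), \code{lipid_class}
#' (lipid_associated / non_lipid / tentative_lipid / tentative_non_lipid /
#' unknown) and \code{genus}. Unknown extra columns are preserved. Virus
#' entries must name a host domain; cellular entries must not carry a virus
#' family.
#'
#' @param path TSV file path.
#' @return Metadata data.frame.
#' @export
read_metadata <- function(path) {
  df <- read_required_tsv(path, c("genome_id", "name", "entity_class",
                                  "virus_family", "host_domain",
                                  "lipid_class", "genus"), "metadata")
  validate_metadata(df)
}

validate_metadata <- function(df) {
  bad_class <- setdiff(df$entity_class, c("virus", "bacterium", "archaeon"))
  if (length(bad_class) > 0)
    stop("unknown entity_class value(s): ", paste(bad_class, collapse = ", "))
  v <- df$entity_class == "virus"
  if (any(v & (is.na(df$host_domain) | df$host_domain == "none")))
    stop("virus entries must have host_domain Bacteria or Archaea: ",
         paste(df$genome_id[v & (is.na(df$host_domain) |
                                   df$host_domain == "none")], collapse = ", "))
  cellular_fam <- !v & !(is.na(df$virus_family) | df$virus_family == "none")
  if (any(cellular_fam))
    stop("cellular entries must not carry a virus_family: ",
         paste(df$genome_id[cellular_fam], collapse = ", "))
  df
}

#' Read an orthogroup membership table
#'
#' TSV with columns \code{protein_id} and \code{group_id}; each protein maps
#' to at most one group.
#'
#' @param path TSV file path.
#' @param proteins optional protein table; member ids not found there are
#'   reported with a warning (dangling members).
#' @return data.frame with \code{protein_id}, \code{group_id}.
#' @export
read_orthogroups <- function(path, proteins = NULL) {
  df <- read_required_tsv(path, c("protein_id", "group_id"), "orthogroup")
  if (anyDuplicated(df$protein_id))
    stop("protein(s) mapped to more than one orthogroup: ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]),
               collapse = ", "))
  if (!is.null(proteins)) {
    dangling <- setdiff(df$protein_id, proteins$protein_id)
    if (length(dangling) > 0)
      warning(length(dangling), " orthogroup member(s) do not resolve to a ",
              "loaded protein: ", paste(utils::head(dangling, 5),
                                        collapse = ", "))
  }
  df
}

#' Read a prophage-region table
#'
#' TSV with columns \code{genome_id} (cellular genome), \code{region_id} and
#' \code{protein_id} (one row per protein inside a region).
#'
#' @param path TSV file path.
#' @return data.frame with \code{genome_id}, \code{region_id},
#'   \code{protein_id}.
#' @export
read_prophages <- function(path) {
  read_required_tsv(path, c("genome_id", "region_id", "protein_id"),
                    "prophage")
}

# Serialize a named histogram like c(`0`=3,`1`=2) to "0:3;1:2" and back.
serialize_hist <- function(h) paste(names(h), h, sep = ":", collapse = ";")
deserialize_hist <- function(s) {
  parts <- strsplit(strsplit(s, ";")[[1]], ":")
  stats::setNames(as.integer(vapply(parts, `[`, "", 2)),
                  vapply(parts, `[`, "", 1))
}

#' Write a genome census table
#'
#' Tab-separated, deterministic column order, with a provenance comment
#' header. Fractions are serialized with 4 decimal places; the TM-count
#' histogram is serialized as \code{k:count} pairs joined by \code{;}
#' (coordinates of TM segments throughout the package are 1-based inclusive).
#' Round-trips losslessly through \code{\link{read_census}} at that precision.
#'
#' @param census a census table from \code{\link{genome_census}}.
#' @param path output path.
#' @param provenance optional named character vector written as
#'   \code{# key: value} comment lines.
#' @return \code{path}, invisibly.
#' @export
write_census <- function(census, path, provenance = NULL) {
  stopifnot(nrow(census) > 0)
  df <- data.frame(
    genome_id = census$genome_id,
    n_proteins = census$n_proteins,
    n_tm = census$n_tm,
    tm_fraction = sprintf("%.4f", census$tm_fraction),
    n_in_orthogroups = census$n_in_orthogroups,
    tm_conserved = census$tm_conserved,
    tm_not_conserved = census$tm_not_conserved,
    non_tm_conserved = census$non_tm_conserved,
    non_tm_not_conserved = census$non_tm_not_conserved,
    histogram = vapply(census$histogram, serialize_hist, ""),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome census table written by \code{\link{write_census}}
#'
#' @param path TSV file path.
#' @return Census table of class \code{genome_census}.
#' @export
read_census <- function(path) {
  df <- read_required_tsv(path, c("genome_id", "n_proteins", "n_tm",
                                  "tm_fraction", "n_in_orthogroups",
                                  "histogram"), "census")
  df$tm_fraction <- as.numeric(df$tm_fraction)
  df$histogram <- I(lapply(df$histogram, deserialize_hist))
  class(df) <- c("genome_census", "data.frame")
  df
}
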