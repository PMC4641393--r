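# The Viral Quotient (VQ): how virus-specific a gene family is, measured from
# the genome-frequencies of its homologs among lytic virus genomes and
# cellular genomes, with matches in integrated prophage regions credited to
# the viral side.

#' Compute the Viral Quotient of one orthogroup
#'
#' Frequencies are fractions of genomes in each universe containing at least
#' one member of the group: \code{f_viral} over the virus genome universe,
#' \code{f_cellular} over the cellular universe (counting every cellular
#' genome with a match, inside or outside prophage regions), and
#' \code{f_prophage} over the cellular universe counting genomes whose
#' matches include a prophage-region protein. The prophage correction adds
#' the prophage frequency to the viral side:
#' \deqn{VQ = (f_v + f_p) / (f_v + f_p + f_c)}
#' so a family found only in lytic viruses scores 1.0, one found only outside
#' prophages in cellular genomes scores 0.0, and one found only in prophage
#' regions scores 0.5.
#'
#' @param member_ids protein ids belonging to the orthogroup.
#' @param proteins protein table mapping \code{protein_id} to
#'   \code{genome_id}.
#' @param metadata metadata table classifying each genome
#'   (\code{entity_class}).
#' @param prophages optional prophage table (\code{genome_id},
#'   \code{region_id}, \code{protein_id}).
#' @param n_virus,n_cellular universe sizes (numbers of virus and cellular
#'   genomes the frequencies are relative to); default: counts in
#'   \code{metadata}.
#' @param group_id label carried into the result.
#' @param prophage_mode \code{"viral_side"} (default) credits the prophage
#'   frequency to the viral side only, as in the displayed formula.
#'   \code{"both_sides"} is an alternative reading that also adds it to the
#'   denominator a second time, i.e. \eqn{(f_v + f_p)/(f_v + f_c + 2 f_p)};
#'   it preserves the virus-only and cellular-only anchors but scores a
#'   prophage-only family 1/3 instead of 1/2.
#' @return List of class \code{vq_record}: \code{group_id}, \code{f_viral},
#'   \code{f_cellular}, \code{f_prophage}, \code{vq}.
#' @export
compute_vq <- function(member_ids, proteins, metadata, prophages = NULL,
                       n_virus = NULL, n_cellular = NULL,
                       group_id = NA_character_,
                       prophage_mode = c("viral_side", "both_sides")) {
  prophage_mode <- match.arg(prophage_mode)
  gid <- stats::setNames(proteins$genome_id, proteins$protein_id)
  member_genomes <- unname(gid[member_ids])
  if (anyNA(member_genomes) || length(member_ids) == 0)
    stop("orthogroup ", group_id, " has unresolvable or zero members")
  cls <- stats::setNames(metadata$entity_class, metadata$genome_id)
  mcls <- cls[member_genomes]
  if (anyNA(mcls))
    stop("member genome(s) absent from metadata: ",
         paste(unique(member_genomes[is.na(mcls)]), collapse = ", "))
  if (is.null(n_virus)) n_virus <- sum(cls == "virus")
  if (is.null(n_cellular)) n_cellular <- sum(cls != "virus")
  virus_genomes <- unique(member_genomes[mcls == "virus"])
  cellular_genomes <- unique(member_genomes[mcls != "virus"])
  prophage_ids <- if (is.null(prophages)) character(0) else
    prophages$protein_id
  prophage_genomes <- unique(member_genomes[mcls != "virus" &
                                              member_ids %in% prophage_ids])
  f_v <- length(virus_genomes) / n_virus
  f_c <- length(cellular_genomes) / n_cellular
  f_p <- length(prophage_genomes) / n_cellular
  denom <- if (prophage_mode == "viral_side") f_v + f_p + f_c
  else f_v + 2 * f_p + f_c
  if (denom == 0) stop("orthogroup ", group_id, " matches no genome")
  structure(list(group_id = group_id, f_viral = f_v, f_cellular = f_c,
                 f_prophage = f_p, vq = (f_v + f_p) / denom),
            class = "vq_record")
}

#' @export
print.vq_record <- function(x, ...) {
  cat(sprintf("VQ record %s: f_viral %.3f, f_cellular %.3f, f_prophage %.3f -> VQ %.3f (%s)\n",
              x$group_id, x$f_viral, x$f_cellular, x$f_prophage, x$vq,
              classify_vq(x)))
  invisible(x)
}

#' Classify an orthogroup by its Viral Quotient
#'
#' \code{viral_only} at VQ = 1 (seen only in lytic viruses);
#' \code{predominantly_viral} for 0.5 <= VQ < 1 (more homologs among viruses
#' and prophages than in non-prophage cellular chromosome); and
#' \code{predominantly_cellular} below 0.5. The boundary VQ = 0.5 is placed
#' with the viral class because a family occurring only in prophage regions
#' scores exactly 0.5 and is phage-derived by construction.
#'
#' @param record a \code{vq_record} (or a bare VQ value).
#' @return One of \code{"viral_only"}, \code{"predominantly_viral"},
#'   \code{"predominantly_cellular"}.
#' @export
classify_vq <- function(record) {
  vq <- if (inherits(record, "vq_record")) record$vq else record
  stopifnot(vq >= 0, vq <= 1)
  if (vq == 1) "viral_only"
  else if (vq >= 0.5) "predominantly_viral"
  else "predominantly_cellular"
}

#' Viral Quotients for every orthogroup
#'
#' @param orthogroups membership table (\code{protein_id}, \code{group_id}).
#' @param proteins protein table.
#' @param metadata metadata table.
#' @param prophages optional prophage table.
#' @return data.frame with one row per group: \code{group_id}, the three
#'   frequencies, \code{vq} and \code{vq_class}.
#' @export
vq_table <- function(orthogroups, proteins, metadata, prophages = NULL) {
  groups <- split(orthogroups$protein_id, orthogroups$group_id)
  cls <- stats::setNames(metadata$entity_class, metadata$genome_id)
  n_virus <- sum(cls == "virus")
  n_cellular <- sum(cls != "virus")
  rows <- lapply(names(groups), function(g) {
    r <- compute_vq(groups[[g]], proteins, metadata, prophages,
                    n_virus, n_cellular, group_id = g)
    data.frame(group_id = g, f_viral = r$f_viral, f_cellular = r$f_cellular,
               f_prophage = r$f_prophage, vq = r$vq,
               vq_class = classify_vq(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
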