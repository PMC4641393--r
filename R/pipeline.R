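# End-to-end pipeline: simulate (or load) -> predict -> census -> VQ ->
# group comparisons, writing all tables with provenance headers.

provenance <- function(seed, extra = NULL) {
  c(package = paste0("tmcensus ",
                     as.character(utils::packageVersion("tmcensus"))),
    seed = as.character(seed), extra)
}

write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(prov), ": ", prov), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits one protein FASTA per genome plus metadata, orthogroup, prophage and
#' ground-truth TSVs in the layout the readers expect.
#'
#' @param dataset output of \code{\link{generate_synthetic}}.
#' @param dir output directory (created if absent).
#' @param seed recorded in the provenance headers.
#' @return \code{dir}, invisibly.
#' @export
write_synthetic <- function(dataset, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta_dir <- file.path(dir, "proteomes")
  dir.create(fasta_dir, showWarnings = FALSE)
  prov <- provenance(seed)
  for (gid in unique(dataset$proteins$genome_id)) {
    p <- dataset$proteins[dataset$proteins$genome_id == gid, ]
    aa <- Biostrings::AAStringSet(p$sequence)
    names(aa) <- paste0(gid, "|", p$protein_id)
    Biostrings::writeXStringSet(aa, file.path(fasta_dir,
                                              paste0(gid, ".faa")))
  }
  write_tsv_prov(dataset$metadata, file.path(dir, "metadata.tsv"), prov)
  write_tsv_prov(dataset$orthogroups, file.path(dir, "orthogroups.tsv"),
                 prov)
  if (!is.null(dataset$prophages) && nrow(dataset$prophages) > 0)
    write_tsv_prov(dataset$prophages, file.path(dir, "prophages.tsv"), prov)
  write_tsv_prov(dataset$truth, file.path(dir, "truth.tsv"), prov)
  invisible(dir)
}

#' Run the full census pipeline
#'
#' Executes simulate (unless an input directory of proteomes and tables is
#' supplied) -> topology prediction -> per-genome census -> Viral Quotient ->
#' headline group comparisons, writing every table under \code{out}. The
#' summary report contains the virus-vs-cell TM-count histogram test, the
#' lipid-association correlation and MWW test, and the VQ class distribution.
#'
#' @param out output directory.
#' @param spec a \code{\link{synthetic_spec}} used when simulating.
#' @param config a \code{\link{predictor_config}}.
#' @param seed master seed (overrides \code{spec$seed}).
#' @return Invisibly, a list with \code{census}, \code{vq}, \code{report}.
#' @export
run_pipeline <- function(out, spec = synthetic_spec(),
                         config = predictor_config(), seed = spec$seed) {
  spec$seed <- seed
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance(seed)

  dataset <- generate_synthetic(spec)
  write_synthetic(dataset, file.path(out, "data"), seed)

  predictions <- predict_proteome(dataset$proteins, config)
  write_predictions(predictions, file.path(out, "predictions.tsv"))

  census <- genome_census(dataset$proteins, predictions,
                          dataset$orthogroups)
  write_census(census, file.path(out, "census.tsv"), prov)

  pooled_v <- aggregate_histogram(
    census[census$genome_id %in%
             dataset$metadata$genome_id[dataset$metadata$entity_class ==
                                          "virus"], ])
  pooled_c <- aggregate_histogram(
    census[census$genome_id %in%
             dataset$metadata$genome_id[dataset$metadata$entity_class !=
                                          "virus"], ])
  write_tsv_prov(data.frame(tm_count = names(pooled_v), virus = pooled_v,
                            cellular = pooled_c),
                 file.path(out, "pooled_histograms.tsv"), prov)

  vq <- vq_table(dataset$orthogroups, dataset$proteins, dataset$metadata,
                 dataset$prophages)
  write_tsv_prov(vq, file.path(out, "vq.tsv"), prov)

  virus_census <- census[census$genome_id %in%
                           dataset$metadata$genome_id[
                             dataset$metadata$entity_class == "virus"], ]
  meta_v <- dataset$metadata[dataset$metadata$entity_class == "virus", ]
  lipid <- meta_v$genome_id[meta_v$lipid_class %in%
                              c("lipid_associated", "tentative_lipid")]
  hist_test <- chisq_hist_test(pooled_v, pooled_c)
  mww_lipid <- if (length(lipid) > 0 &&
                   length(lipid) < nrow(virus_census))
    mww_test(virus_census$tm_fraction[virus_census$genome_id %in% lipid],
             virus_census$tm_fraction[!virus_census$genome_id %in% lipid])
  else NULL
  lipid_cor <- tryCatch(tm_correlate(virus_census, meta_v, "lipid_binary"),
                        error = function(e) NA_real_)
  consistency <- tryCatch(
    orthogroup_consistency(predictions, dataset$orthogroups),
    error = function(e) NULL)

  report <- c(
    sprintf("genomes censused: %d (%d virus, %d cellular)",
            nrow(census), nrow(virus_census),
            nrow(census) - nrow(virus_census)),
    sprintf("virus vs cell TM-count histogram: X^2 = %.4g, df = %d, p = %.3g",
            hist_test$statistic, hist_test$df, hist_test$p_value),
    sprintf("lipid-association point-biserial correlation: %.3f", lipid_cor),
    if (!is.null(mww_lipid))
      sprintf("lipid vs non-lipid MWW: U = %g, p = %.3g", mww_lipid$u,
              mww_lipid$p_value),
    sprintf("VQ classes: %s",
            paste(names(table(vq$vq_class)), table(vq$vq_class),
                  sep = "=", collapse = ", ")),
    if (!is.null(consistency))
      sprintf("orthogroup consistency: %.1f%% uniform",
              100 * consistency$fraction_uniform))
  writeLines(c(paste0("# ", names(prov), ": ", prov), report),
             file.path(out, "report.txt"))
  invisible(list(census = census, vq = vq, report = report))
}
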