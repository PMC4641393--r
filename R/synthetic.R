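# Seeded generator of synthetic proteomes with planted TM topology ground
# truth, genome metadata, orthogroup membership and prophage regions, so the
# whole census pipeline can run and be validated without any external data.

# Residue compositions. TM helices are sampled from a strongly
# hydrophobic-enriched table, loops from a hydrophilic table whose residues
# are all hydropathy-negative (so segment trimming recovers planted helix
# boundaries), and soluble proteins from a mildly hydrophilic average
# composition.
tm_composition <- function() {
  c(L = .24, I = .17, V = .16, F = .11, A = .13, M = .07,
    G = .04, W = .02, C = .02, T = .02, S = .02)
}
loop_composition <- function() {
  c(D = .13, E = .13, N = .08, Q = .07, S = .13, T = .10,
    P = .10, G = .13, H = .03, K = .02, R = .02, Y = .06)
}
soluble_composition <- function() {
  c(A = .07, R = .06, N = .05, D = .07, C = .01, Q = .05, E = .09, G = .08,
    H = .02, I = .03, L = .07, K = .08, M = .02, F = .03, P = .05, S = .09,
    T = .06, W = .01, Y = .03, V = .03)
}

# Internal table of virus families with host domain and virion lipid class,
# weighted roughly as in public dsDNA prokaryotic virus collections (tailed
# bacteriophages dominate).
virus_family_table <- function() {
  data.frame(
    family = c("Myoviridae", "Siphoviridae", "Podoviridae", "Tectiviridae",
               "Corticoviridae", "Plasmaviridae", "Fuselloviridae",
               "Rudiviridae", "Lipothrixviridae", "Ampullaviridae",
               "Globuloviridae", "Bicaudaviridae"),
    host_domain = c("Bacteria", "Bacteria", "Bacteria", "Bacteria",
                    "Bacteria", "Bacteria", "Archaea", "Archaea", "Archaea",
                    "Archaea", "Archaea", "Archaea"),
    lipid_class = c("non_lipid", "non_lipid", "non_lipid", "lipid_associated",
                    "lipid_associated", "lipid_associated",
                    "lipid_associated", "non_lipid", "lipid_associated",
                    "lipid_associated", "tentative_lipid",
                    "tentative_non_lipid"),
    weight = c(.30, .35, .18, .03, .01, .01, .03, .02, .02, .01, .02, .02),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic proteome set
#'
#' All parameters of the generator, with defaults matching the regimes the
#' census is designed around: virus-like genomes plant ~8 % TM proteins with
#' 1-3 segments (lipid-associated virion families plant ~30 %), cell-like
#' genomes plant ~22 % TM proteins with a heavy polytopic tail including
#' secondary modes at 6 and 12 segments, helices average 21 aa, loops carry a
#' planted Lys/Arg excess on the cytoplasmic side, and a small minority of
#' proteins carry an N-terminal signal peptide.
#'
#' @param seed master seed; every genome derives its own substream from it,
#'   so adding genomes does not perturb existing ones.
#' @param n_virus_genomes,n_cellular_genomes genome counts.
#' @param genes_per_genome named list (\code{virus}, \code{cellular}) of
#'   \code{c(mean, dispersion)} for the negative-binomial gene count.
#' @param tm_fraction named vector: target fraction of TM proteins per class.
#' @param tm_fraction_lipid_virus target TM fraction in virus genomes whose
#'   family has a lipid-associated (or tentatively lipid-associated) virion.
#' @param tm_fraction_concentration beta concentration (shape1 + shape2) of
#'   the per-genome TM-fraction target around the class mean. Virus genomes
#'   spread widely around their mean while cellular TM fractions are nearly
#'   constant, so the virus concentration is much lower.
#' @param tm_count_probs named list of named probability vectors over planted
#'   TM-segment counts per class.
#' @param helix_len \code{c(mean, sd, min, max)} of planted helix length (aa,
#'   truncated normal, rounded).
#' @param loop_len_min,loop_len_mean minimum and mean inter-segment loop
#'   length (aa); loop length = min + Poisson(mean - min).
#' @param kr_bias planted excess of Lys/Arg residues per loop on the 'in'
#'   side (positive-inside signal strength).
#' @param signal_rate fraction of proteins carrying a signal peptide.
#' @param soluble_len named list per class: \code{c(mean, sd)} of soluble
#'   protein length (truncated at 50 aa).
#' @param tail_len_mean mean Poisson length of the C-terminal soluble tail
#'   appended to TM proteins.
#' @param conserved_rate probability a protein is assigned to an orthogroup.
#' @param n_orthogroups named vector: orthogroup pool size per class.
#' @param prophage_rate fraction of cellular genomes carrying one prophage
#'   region.
#' @param prophage_size number of proteins in a prophage region.
#' @param prophage_tm_fraction target TM fraction among prophage proteins.
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1,
                           n_virus_genomes = 20, n_cellular_genomes = 10,
                           genes_per_genome = list(
                             virus = c(mean = 80, dispersion = 10),
                             cellular = c(mean = 250, dispersion = 10)),
                           tm_fraction = c(virus = 0.08, cellular = 0.22),
                           tm_fraction_lipid_virus = 0.30,
                           tm_fraction_concentration = c(virus = 25,
                                                         cellular = 400,
                                                         lipid_virus = 80),
                           tm_count_probs = list(
                             virus = c("1" = .70, "2" = .20, "3" = .10),
                             cellular = c("1" = .40, "2" = .14, "3" = .08,
                                          "4" = .06, "5" = .03, "6" = .12,
                                          "7" = .03, "8" = .02, "10" = .02,
                                          "12" = .08, "13" = .01,
                                          "14" = .01)),
                           helix_len = c(mean = 21, sd = 1.5, min = 19,
                                         max = 25),
                           loop_len_min = 10, loop_len_mean = 16,
                           kr_bias = 3,
                           signal_rate = 0.03,
                           soluble_len = list(
                             virus = c(mean = 200, sd = 80),
                             cellular = c(mean = 300, sd = 120)),
                           tail_len_mean = 30,
                           conserved_rate = 0.6,
                           n_orthogroups = c(virus = 300, cellular = 1500),
                           prophage_rate = 0.5, prophage_size = 15,
                           prophage_tm_fraction = 0.10) {
  spec <- list(seed = seed, n_virus_genomes = n_virus_genomes,
               n_cellular_genomes = n_cellular_genomes,
               genes_per_genome = genes_per_genome,
               tm_fraction = tm_fraction,
               tm_fraction_lipid_virus = tm_fraction_lipid_virus,
               tm_fraction_concentration = tm_fraction_concentration,
               tm_count_probs = tm_count_probs, helix_len = helix_len,
               loop_len_min = loop_len_min, loop_len_mean = loop_len_mean,
               kr_bias = kr_bias, signal_rate = signal_rate,
               soluble_len = soluble_len, tail_len_mean = tail_len_mean,
               conserved_rate = conserved_rate,
               n_orthogroups = n_orthogroups,
               prophage_rate = prophage_rate, prophage_size = prophage_size,
               prophage_tm_fraction = prophage_tm_fraction)
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  stopifnot(spec$n_virus_genomes >= 0, spec$n_cellular_genomes >= 0,
            all(spec$tm_fraction >= 0), all(spec$tm_fraction <= 1),
            spec$signal_rate >= 0, spec$signal_rate <= 1,
            spec$conserved_rate >= 0, spec$conserved_rate <= 1,
            spec$prophage_rate >= 0, spec$prophage_rate <= 1)
  for (p in spec$tm_count_probs)
    if (abs(sum(p) - 1) > 1e-8)
      stop("tm_count_probs must be normalized probability vectors")
  hl <- spec$helix_len
  if (hl["min"] > hl["max"] || hl["min"] < 5)
    stop("infeasible helix length bounds")
  if (spec$loop_len_min < 1 || spec$loop_len_mean < spec$loop_len_min)
    stop("infeasible loop length parameters")
  invisible(spec)
}

# Per-genome TM-fraction target: beta-distributed around the class mean with
# the class concentration (degenerate at the mean for edge cases).
draw_tm_target <- function(mean, concentration) {
  if (mean <= 0 || mean >= 1 || !is.finite(concentration)) return(mean)
  stats::rbeta(1, mean * concentration, (1 - mean) * concentration)
}

sample_residues <- function(n, comp) {
  if (n == 0) return(character(0))
  sample(names(comp), n, replace = TRUE, prob = comp)
}

rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Build one TM protein with k planted helices. Returns list(sequence,
# segments, orientation, signal).
make_tm_protein <- function(k, spec, with_signal = FALSE) {
  hl <- spec$helix_len
  helix_lens <- rtrunc_norm_int(k, hl["mean"], hl["sd"], hl["min"], hl["max"])
  loop_lens <- spec$loop_len_min +
    stats::rpois(k + 1, spec$loop_len_mean - spec$loop_len_min)
  loop_lens[k + 1] <- loop_lens[k + 1] + stats::rpois(1, spec$tail_len_mean)
  orientation <- sample(c("in", "out"), 1)
  loops <- lapply(loop_lens, function(L)
    sample_residues(L, loop_composition()))
  for (j in seq_len(k + 1)) {
    side <- if ((j %% 2) == 1) orientation else
      if (orientation == "in") "out" else "in"
    if (side == "in" && loop_lens[j] >= spec$kr_bias) {
      # place the planted K/R excess in the membrane-proximal part of the
      # loop, where the positive-inside enrichment lives
      L <- loop_lens[j]
      near <- integer(0)
      if (j <= k) near <- c(near, seq(to = L, length.out = min(L, 12)))
      if (j > 1) near <- c(near, seq_len(min(L, 12)))
      near <- unique(near)
      pos <- if (length(near) > spec$kr_bias)
        sample(near, spec$kr_bias) else near
      loops[[j]][pos] <- sample(c("K", "R"), length(pos), replace = TRUE)
    }
  }
  prefix <- character(0)
  if (with_signal)
    prefix <- c("M", "K", sample_residues(1, loop_composition()),
                sample(c("L", "A", "V", "I", "F"), 9, replace = TRUE),
                "A", "Q", "A")
  parts <- character(0)
  segs <- matrix(0L, nrow = k, ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  pos <- length(prefix)
  for (j in seq_len(k)) {
    parts <- c(parts, loops[[j]])
    pos <- pos + loop_lens[j]
    parts <- c(parts, sample_residues(helix_lens[j], tm_composition()))
    segs[j, ] <- c(pos + 1, pos + helix_lens[j])
    pos <- pos + helix_lens[j]
  }
  parts <- c(parts, loops[[k + 1]])
  list(sequence = paste(c(prefix, parts), collapse = ""),
       segments = segs, orientation = orientation, signal = with_signal)
}

make_soluble_protein <- function(spec, class, with_signal = FALSE) {
  sl <- spec$soluble_len[[class]]
  L <- max(50, round(stats::rnorm(1, sl["mean"], sl["sd"])))
  prefix <- character(0)
  if (with_signal)
    prefix <- c("M", "K", sample_residues(1, loop_composition()),
                sample(c("L", "A", "V", "I", "F"), 9, replace = TRUE),
                "A", "Q", "A")
  list(sequence = paste(c(prefix,
                          sample_residues(L, soluble_composition())),
                        collapse = ""),
       segments = matrix(0L, 0, 2, dimnames = list(NULL, c("start", "end"))),
       orientation = "in", signal = with_signal)
}

# Generate the proteins of one genome; class is "virus" or "cellular";
# target_tm overrides the class tm_fraction (used for lipid-associated virus
# families and prophage regions).
make_genome_proteins <- function(genome_id, n_genes, class, target_tm, spec,
                                 id_prefix = "p") {
  probs <- spec$tm_count_probs[[class]]
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    is_tm <- stats::runif(1) < target_tm
    with_signal <- stats::runif(1) < spec$signal_rate
    p <- if (is_tm) {
      k <- as.integer(sample(names(probs), 1, prob = probs))
      make_tm_protein(k, spec, with_signal)
    } else make_soluble_protein(spec, class, with_signal)
    rows[[i]] <- data.frame(
      protein_id = paste0(genome_id, "_", id_prefix, i),
      genome_id = genome_id, sequence = p$sequence,
      n_tm = nrow(p$segments),
      segments = paste(p$segments[, 1], p$segments[, 2], sep = "-",
                       collapse = ";"),
      orientation = p$orientation, signal = p$signal,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate a synthetic proteome set
#'
#' Produces protein sequences with planted TM topology for a set of
#' virus-like and cell-like genomes, plus genome metadata, orthogroup
#' membership, prophage regions inside cellular genomes, and the full ground
#' truth. Deterministic for a given spec: each genome draws from its own
#' seed substream.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return List with \code{proteins} (protein table as from
#'   \code{\link{read_proteomes}}), \code{metadata}, \code{orthogroups},
#'   \code{prophages}, and \code{truth} (per-protein planted topology:
#'   \code{n_tm}, \code{segments} serialized \code{start-end;...},
#'   \code{orientation}, \code{signal}).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  validate_synthetic_spec(spec)
  fam_tab <- virus_family_table()
  truth <- list(); meta <- list(); ortho <- list(); proph <- list()
  nv <- spec$n_virus_genomes; nc <- spec$n_cellular_genomes
  for (i in seq_len(nv + nc)) {
    is_virus <- i <= nv
    gid <- if (is_virus) sprintf("V%03d", i) else sprintf("C%03d", i - nv)
    # virus and cellular genomes occupy disjoint substream index ranges so
    # growing one class never reseeds the other
    stream <- if (is_virus) i else 1000000L + (i - nv)
    res <- with_seed(substream_seed(spec$seed, stream), {
      if (is_virus) {
        fam <- fam_tab[sample(nrow(fam_tab), 1, prob = fam_tab$weight), ]
        lipid <- fam$lipid_class %in% c("lipid_associated", "tentative_lipid")
        target <- if (lipid)
          draw_tm_target(spec$tm_fraction_lipid_virus,
                         spec$tm_fraction_concentration[["lipid_virus"]])
        else draw_tm_target(spec$tm_fraction[["virus"]],
                            spec$tm_fraction_concentration[["virus"]])
        gp <- spec$genes_per_genome$virus
        n_genes <- max(5, stats::rnbinom(1, mu = gp["mean"],
                                         size = gp["dispersion"]))
        prot <- make_genome_proteins(gid, n_genes, "virus", target, spec)
        md <- data.frame(genome_id = gid,
                         name = paste0(fam$family, " phage ", gid),
                         entity_class = "virus", virus_family = fam$family,
                         host_domain = fam$host_domain,
                         lipid_class = fam$lipid_class,
                         genus = paste0(fam$family, "_genus_",
                                        sample(3, 1)),
                         stringsAsFactors = FALSE)
        pool <- "virus"
        pr <- NULL
      } else {
        cls <- sample(c("bacterium", "archaeon"), 1, prob = c(.8, .2))
        gp <- spec$genes_per_genome$cellular
        n_genes <- max(20, stats::rnbinom(1, mu = gp["mean"],
                                          size = gp["dispersion"]))
        cell_target <- draw_tm_target(
          spec$tm_fraction[["cellular"]],
          spec$tm_fraction_concentration[["cellular"]])
        prot <- make_genome_proteins(gid, n_genes, "cellular", cell_target,
                                     spec)
        pr <- NULL
        if (stats::runif(1) < spec$prophage_rate && spec$prophage_size > 0) {
          ppro <- make_genome_proteins(gid, spec$prophage_size, "virus",
                                       spec$prophage_tm_fraction, spec,
                                       id_prefix = "pp")
          prot <- rbind(prot, ppro)
          pr <- data.frame(genome_id = gid,
                           region_id = paste0(gid, "_prophage1"),
                           protein_id = ppro$protein_id,
                           stringsAsFactors = FALSE)
        }
        md <- data.frame(genome_id = gid, name = paste0("Cell ", gid),
                         entity_class = cls, virus_family = "none",
                         host_domain = "none",
                         lipid_class = "unknown",
                         genus = paste0("Genus_",
                                        sample(ceiling(spec$n_cellular_genomes *
                                                         0.8), 1)),
                         stringsAsFactors = FALSE)
        pool <- "cellular"
      }
      # orthogroup assignment: prophage proteins draw from the virus pool
      in_prophage <- if (is.null(pr)) rep(FALSE, nrow(prot)) else
        prot$protein_id %in% pr$protein_id
      conserved <- stats::runif(nrow(prot)) < spec$conserved_rate
      pool_of <- ifelse(in_prophage, "virus", pool)
      grp <- ifelse(conserved,
                    ifelse(pool_of == "virus",
                           sprintf("VOG%04d",
                                   sample.int(spec$n_orthogroups[["virus"]],
                                              nrow(prot), replace = TRUE)),
                           sprintf("COG%05d",
                                   sample.int(spec$n_orthogroups[["cellular"]],
                                              nrow(prot), replace = TRUE))),
                    NA_character_)
      og <- data.frame(protein_id = prot$protein_id[conserved],
                       group_id = grp[conserved], stringsAsFactors = FALSE)
      list(prot = prot, md = md, og = og, pr = pr)
    })
    truth[[i]] <- res$prot; meta[[i]] <- res$md
    ortho[[i]] <- res$og; proph[[i]] <- res$pr
  }
  truth_df <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  proteins <- truth_df[, c("protein_id", "genome_id", "sequence")]
  proteins$length <- nchar(proteins$sequence)
  list(proteins = proteins,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       orthogroups = do.call(rbind, c(ortho, list(make.row.names = FALSE))),
       prophages = {
         keep <- proph[!vapply(proph, is.null, TRUE)]
         if (length(keep) == 0) NULL else
           do.call(rbind, c(keep, list(make.row.names = FALSE)))
       },
       truth = truth_df[, c("protein_id", "genome_id", "n_tm", "segments",
                            "orientation", "signal")])
}

#' Ground truth as a topology set
#'
#' Converts generator ground truth to a \code{tm_topology_set} so the census
#' can be run on planted topology directly, bypassing prediction.
#'
#' @param truth the \code{truth} component of
#'   \code{\link{generate_synthetic}} output.
#' @return A \code{tm_topology_set} with \code{source = "truth"}.
#' @export
truth_topology_set <- function(truth) {
  preds <- lapply(seq_len(nrow(truth)), function(i) {
    segs <- if (truth$n_tm[i] == 0)
      matrix(0L, 0, 2, dimnames = list(NULL, c("start", "end")))
    else {
      se <- do.call(rbind,
                    lapply(strsplit(strsplit(truth$segments[i], ";")[[1]],
                                    "-"), as.integer))
      colnames(se) <- c("start", "end")
      se
    }
    structure(list(protein_id = truth$protein_id[i], segments = segs,
                   n_tm = truth$n_tm[i],
                   n_terminal_side = truth$orientation[i],
                   signal_peptide = truth$signal[i], source = "truth"),
              class = "tm_topology")
  })
  topology_set(preds, genome_id = truth$genome_id)
}

#' Perturb a protein into a synthetic orthogroup
#'
#' Creates homolog copies of a protein by loop-restricted point substitutions
#' and rare single-residue loop indels, preserving the planted helices (and
#' therefore the planted TM count) exactly; segment coordinates are updated
#' for the indels.
#'
#' @param sequence amino-acid string.
#' @param segments planted TM segments (start/end matrix; may have 0 rows).
#' @param n_copies number of homolog copies.
#' @param indel_rate per-loop-residue probability of a single-residue
#'   insertion or deletion, in [0, 0.05].
#' @param sub_rate per-loop-residue substitution probability.
#' @param seed RNG seed.
#' @return List of length \code{n_copies}; each element has \code{sequence}
#'   and \code{segments}.
#' @export
perturb_orthogroup <- function(sequence, segments, n_copies,
                               indel_rate = 0.01, sub_rate = 0.05, seed = 1) {
  stopifnot(indel_rate >= 0, indel_rate <= 0.05)
  res <- strsplit(sequence, "")[[1]]
  in_helix <- rep(FALSE, length(res))
  if (nrow(segments) > 0)
    for (j in seq_len(nrow(segments)))
      in_helix[segments[j, 1]:segments[j, 2]] <- TRUE
  with_seed(seed, lapply(seq_len(n_copies), function(cp) {
    out <- lapply(seq_along(res), function(i) {
      if (in_helix[i]) return(res[i])
      r <- res[i]
      if (stats::runif(1) < sub_rate)
        r <- sample_residues(1, loop_composition())
      u <- stats::runif(1)
      if (u < indel_rate / 2) return(character(0))            # deletion
      if (u < indel_rate) return(c(r, sample_residues(1, loop_composition())))
      r
    })
    lens <- lengths(out)
    newpos <- cumsum(lens)
    segs <- segments
    if (nrow(segs) > 0) for (j in seq_len(nrow(segs))) {
      segs[j, 1] <- newpos[segs[j, 1]] - lens[segs[j, 1]] + 1
      segs[j, 2] <- newpos[segs[j, 2]]
    }
    list(sequence = paste(unlist(out), collapse = ""), segments = segs)
  }))
}
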