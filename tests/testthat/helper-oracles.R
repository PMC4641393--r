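# Independent oracle implementations used to cross-check the package's
# operations. These are deliberately naive (explicit loops, direct formulas)
# and share no code with the implementation.

# Brute-force TM segment caller: scores every window with explicit loops,
# marks covered residues, merges, trims, splits and filters by direct
# translation of the calling rules.
oracle_call_segments <- function(sequence, config = predictor_config()) {
  kd <- kyte_doolittle()
  res <- strsplit(sequence, "")[[1]]
  h <- numeric(length(res))
  for (i in seq_along(res)) h[i] <- kd[[res[i]]]
  n <- length(h); w <- config$window
  covered <- rep(FALSE, n)
  if (n >= w) for (s in 1:(n - w + 1)) {
    tot <- 0
    for (j in s:(s + w - 1)) tot <- tot + h[j]
    if (tot / w >= config$threshold - 1e-9) covered[s:(s + w - 1)] <- TRUE
  }
  # runs of covered residues
  runs <- list()
  i <- 1
  while (i <= n) {
    if (covered[i]) {
      j <- i
      while (j < n && covered[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  # merge runs with gap < merge_gap
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0 &&
        r[1] - merged[[length(merged)]][2] - 1 < config$merge_gap)
      merged[[length(merged)]][2] <- r[2]
    else merged[[length(merged) + 1]] <- r
  }
  # trim, split long, filter short
  split_rec <- function(s, e) {
    if (e - s + 1 <= config$max_len) return(list(c(s, e)))
    best <- s + 1
    for (q in (s + 1):(e - 1)) if (h[q] < h[best]) best <- q
    c(split_rec(s, best - 1), split_rec(best + 1, e))
  }
  out <- list()
  for (r in merged) {
    s <- r[1]; e <- r[2]
    while (s <= e && h[s] < config$trim_cutoff) s <- s + 1
    while (e >= s && h[e] < config$trim_cutoff) e <- e - 1
    if (s > e) next
    for (piece in split_rec(s, e))
      if (piece[2] - piece[1] + 1 >= config$min_len)
        out[[length(out) + 1]] <- piece
  }
  if (length(out) == 0)
    return(matrix(0L, 0, 2, dimnames = list(NULL, c("start", "end"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m[order(m[, 1]), , drop = FALSE]
}

# Direct evaluation of the Viral Quotient formula from genome match sets.
oracle_vq <- function(n_virus_matched, n_cellular_matched,
                      n_prophage_matched, n_virus, n_cellular) {
  fv <- n_virus_matched / n_virus
  fc <- n_cellular_matched / n_cellular
  fp <- n_prophage_matched / n_cellular
  (fv + fp) / (fv + fp + fc)
}

# Exhaustive two-sided Mann-Whitney p-value: iterate over every subset of
# size n via bitmasks, compute U from midranks, and count configurations at
# least as extreme as observed.
oracle_mww_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  dev_obs <- abs(u_obs - n * m / 2)
  total <- 0; extreme <- 0
  for (mask in 0:(2^(n + m) - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n + m - 1))) > 0)
    if (length(idx) != n) next
    total <- total + 1
    if (abs(u_of(idx) - n * m / 2) >= dev_obs - 1e-9) extreme <- extreme + 1
  }
  extreme / total
}

# Pearson chi-squared statistic on a 2 x K table by the direct formula.
oracle_pearson_chisq <- function(obs) {
  tot <- sum(obs)
  stat <- 0
  for (i in seq_len(nrow(obs))) for (j in seq_len(ncol(obs))) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / tot
    stat <- stat + (obs[i, j] - e)^2 / e
  }
  stat
}

# Minimal protein/prediction fixtures -----------------------------------

# A protein table built directly from sequences.
make_protein_table <- function(sequences, genome_id = "G1",
                               prefix = "prot") {
  data.frame(protein_id = paste0(prefix, seq_along(sequences)),
             genome_id = genome_id, sequence = sequences,
             length = nchar(sequences), stringsAsFactors = FALSE)
}

# A topology set with given TM counts (segments are synthesized as
# non-overlapping placeholders).
make_count_predictions <- function(protein_ids, n_tm,
                                   genome_id = NA_character_,
                                   source = "builtin") {
  preds <- lapply(seq_along(protein_ids), function(i) {
    k <- n_tm[i]
    segs <- if (k == 0)
      matrix(0L, 0, 2, dimnames = list(NULL, c("start", "end")))
    else cbind(start = seq(1, by = 30, length.out = k),
               end = seq(21, by = 30, length.out = k))
    structure(list(protein_id = protein_ids[i], segments = segs,
                   n_tm = as.integer(k), n_terminal_side = "in",
                   signal_peptide = FALSE, source = source),
              class = "tm_topology")
  })
  tmcensus:::topology_set(preds, genome_id = genome_id)
}

# Viral Quotient fixtures: a universe of nv virus and nc cellular genomes
# with one protein per genome; orthogroup members are placed by genome index.
vq_universe <- function(nv = 10, nc = 10) {
  gids <- c(sprintf("V%02d", seq_len(nv)), sprintf("C%02d", seq_len(nc)))
  proteins <- data.frame(protein_id = paste0(gids, "_p1"), genome_id = gids,
                         sequence = "MKLVA", length = 5,
                         stringsAsFactors = FALSE)
  metadata <- data.frame(
    genome_id = gids, name = gids,
    entity_class = c(rep("virus", nv), rep("bacterium", nc)),
    virus_family = c(rep("Myoviridae", nv), rep("none", nc)),
    host_domain = c(rep("Bacteria", nv), rep("none", nc)),
    lipid_class = c(rep("non_lipid", nv), rep("unknown", nc)),
    genus = "g", stringsAsFactors = FALSE)
  list(proteins = proteins, metadata = metadata,
       virus_ids = gids[seq_len(nv)], cell_ids = gids[nv + seq_len(nc)])
}

member_of <- function(u, virus_idx = integer(0), cell_idx = integer(0)) {
  paste0(c(u$virus_ids[virus_idx], u$cell_ids[cell_idx]), "_p1")
}

prophage_table <- function(u, cell_idx) {
  data.frame(genome_id = u$cell_ids[cell_idx],
             region_id = paste0(u$cell_ids[cell_idx], "_r1"),
             protein_id = paste0(u$cell_ids[cell_idx], "_p1"),
             stringsAsFactors = FALSE)
}

# Random protein-like sequence from loosely realistic composition.
random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
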