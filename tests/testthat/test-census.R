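test_that("genome census computes counts, fractions and capped histograms", {
  prot <- make_protein_table(replicate(10, random_sequence(40)))
  preds <- make_count_predictions(prot$protein_id,
                                  c(1, 2, rep(0, 8)), "G1")
  cen <- genome_census(prot, preds)
  expect_equal(cen$n_tm, 2)
  expect_equal(cen$tm_fraction, 0.2)
  expect_equal(cen$n_proteins, 10)

  prot5 <- make_protein_table(replicate(5, random_sequence(40)))
  preds5 <- make_count_predictions(prot5$protein_id, c(0, 1, 1, 2, 6), "G1")
  cen5 <- genome_census(prot5, preds5, cap = 4)
  h <- cen5$histogram[[1]]
  expect_equal(unname(h[c("0", "1", "2", "3", "4", "4+")]),
               c(1L, 2L, 1L, 0L, 0L, 1L))

  # a genome where nothing spans the membrane
  preds0 <- make_count_predictions(prot5$protein_id, rep(0, 5), "G1")
  expect_equal(genome_census(prot5, preds0)$tm_fraction, 0)
})

test_that("genome census enforces prediction coverage and its invariants", {
  prot <- make_protein_table(replicate(4, random_sequence(30)))
  preds <- make_count_predictions(prot$protein_id[1:3], c(1, 0, 2), "G1")
  expect_error(genome_census(prot, preds), "prot4")

  set.seed(123)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    p <- make_protein_table(replicate(n, random_sequence(30)),
                            genome_id = sample(c("A", "B"), n,
                                               replace = TRUE))
    p <- p[!duplicated(p$protein_id) | !duplicated(p$genome_id), ]
    k <- sample(0:18, nrow(p), replace = TRUE)
    preds <- make_count_predictions(p$protein_id, k, p$genome_id)
    og <- data.frame(
      protein_id = p$protein_id[sample(c(TRUE, FALSE), nrow(p),
                                       replace = TRUE)],
      group_id = "g")
    cen <- genome_census(p, preds, og)
    for (r in seq_len(nrow(cen))) {
      h <- cen$histogram[[r]]
      expect_equal(sum(h), cen$n_proteins[r])
      expect_equal(sum(h[names(h) != "0"]), cen$n_tm[r])
      expect_equal(cen$tm_fraction[r], cen$n_tm[r] / cen$n_proteins[r])
      expect_equal(cen$tm_conserved[r] + cen$tm_not_conserved[r],
                   cen$n_tm[r])
      expect_equal(cen$tm_conserved[r] + cen$non_tm_conserved[r],
                   cen$n_in_orthogroups[r])
    }
  }
})

test_that("census is additive over disjoint genome sets", {
  set.seed(42)
  pa <- make_protein_table(replicate(12, random_sequence(30)), "GA", "a")
  pb <- make_protein_table(replicate(9, random_sequence(30)), "GB", "b")
  ka <- sample(0:3, 12, replace = TRUE); kb <- sample(0:3, 9, replace = TRUE)
  ca <- genome_census(pa, make_count_predictions(pa$protein_id, ka, "GA"))
  cb <- genome_census(pb, make_count_predictions(pb$protein_id, kb, "GB"))
  both <- genome_census(rbind(pa, pb),
                        make_count_predictions(c(pa$protein_id,
                                                 pb$protein_id),
                                               c(ka, kb),
                                               c(pa$genome_id,
                                                 pb$genome_id)))
  expect_equal(sum(both$n_tm), ca$n_tm + cb$n_tm)
  expect_equal(sum(both$n_proteins), ca$n_proteins + cb$n_proteins)
  expect_equal(aggregate_histogram(both),
               ca$histogram[[1]] + cb$histogram[[1]])
})

test_that("pooled histograms sum per bin and normalize to proportions", {
  cen <- structure(data.frame(genome_id = c("A", "B")),
                   class = c("genome_census", "data.frame"))
  cen$histogram <- I(list(c("0" = 5L, "1" = 5L, "2" = 0L),
                          c("0" = 5L, "1" = 0L, "2" = 5L)))
  pooled <- aggregate_histogram(cen)
  expect_equal(unname(pooled), c(10, 5, 5))
  norm <- aggregate_histogram(cen, normalize = TRUE)
  expect_equal(unname(norm), c(0.5, 0.25, 0.25))
  expect_equal(sum(norm), 1)
})

test_that("length stratification bins half-open intervals with a 4+ class", {
  prot <- make_protein_table(c(random_sequence(150), random_sequence(50),
                               random_sequence(250)))
  prot$length <- c(150, 50, 250)
  preds <- make_count_predictions(prot$protein_id, c(0, 1, 6), "G1")
  st <- stratify_by_length(prot, preds, bin_width = 100)
  expect_equal(st$bin_lo, c(0, 100, 200))
  expect_equal(st$tm1[st$bin_lo == 0], 1)
  expect_equal(st$tm4plus[st$bin_lo == 200], 1)
  expect_equal(st$tm0[st$bin_lo == 100], 1)
  expect_equal(sum(st$total), 3)
  expect_true(all(st$tm0 + st$tm1 + st$tm2 + st$tm3 + st$tm4plus ==
                    st$total))
  expect_error(stratify_by_length(prot, preds, bin_width = 5))
})

rep_fixture <- function(sets) {
  # sets: named list genome -> orthogroup ids (one gene per group)
  prot <- do.call(rbind, lapply(names(sets), function(g)
    data.frame(protein_id = paste0(g, "_", seq_along(sets[[g]])),
               genome_id = g,
               sequence = "MKLVA", length = 5, stringsAsFactors = FALSE)))
  og <- do.call(rbind, lapply(names(sets), function(g)
    data.frame(protein_id = paste0(g, "_", seq_along(sets[[g]])),
               group_id = sets[[g]], stringsAsFactors = FALSE)))
  list(proteins = prot, orthogroups = og)
}

test_that("representative selection collapses genomes sharing most genes", {
  # two genomes sharing 19/20 = 95 % of their genes -> one retained
  f <- rep_fixture(list(A = paste0("g", 1:20), B = paste0("g", 2:21)))
  expect_length(select_representatives(f$proteins, f$orthogroups, 0.9), 1)
  # 50 % sharing -> both retained
  f2 <- rep_fixture(list(A = paste0("g", 1:10), B = paste0("g", 6:15)))
  expect_length(select_representatives(f2$proteins, f2$orthogroups, 0.9), 2)
})

test_that("representative groups close transitively (single linkage)", {
  # A-B and B-C above threshold, A-C below -> one component, one kept
  f <- rep_fixture(list(A = paste0("g", 1:25),
                        B = paste0("g", c(1:23, 30, 31)),
                        C = paste0("g", c(8:23, 30:38))))
  shared_ab <- 23 / 25; shared_bc <- 18 / 25; shared_ac <- 16 / 25
  expect_true(shared_ab >= 0.9 && shared_bc < 0.9)
  kept <- select_representatives(f$proteins, f$orthogroups, threshold = 0.7,
                                 seed = 3)
  expect_length(kept, 1)
})

test_that("representative selection is the identity at threshold 1 on distinct sets", {
  f <- rep_fixture(list(A = paste0("a", 1:5), B = paste0("b", 1:5),
                        C = c("a1", "b1", "c1", "c2", "c3")))
  expect_setequal(select_representatives(f$proteins, f$orthogroups, 1.0),
                  c("A", "B", "C"))
})

test_that("retained representatives equal connected components for any seed", {
  f <- rep_fixture(list(A = paste0("g", 1:10), B = paste0("g", 1:10),
                        C = paste0("h", 1:10), D = paste0("h", 1:10),
                        E = paste0("k", 1:10)))
  for (seed in 1:5) {
    kept <- select_representatives(f$proteins, f$orthogroups, 0.9, seed)
    expect_length(kept, 3)
    expect_true(any(kept %in% c("A", "B")))
    expect_true(any(kept %in% c("C", "D")))
    expect_true("E" %in% kept)
  }
})

test_that("genomes without orthogroup-assigned genes are kept with a warning", {
  f <- rep_fixture(list(A = paste0("g", 1:10), B = paste0("g", 1:10)))
  orphan <- data.frame(protein_id = "Z_1", genome_id = "Z",
                       sequence = "MKLVA", length = 5)
  expect_warning(
    kept <- select_representatives(rbind(f$proteins, orphan),
                                   f$orthogroups, 0.9),
    "no orthogroup")
  expect_true("Z" %in% kept)
  expect_length(kept, 2)
})

test_that("cellular representatives are the largest genome per genus", {
  cen <- structure(data.frame(
    genome_id = c("C1", "C2", "C3", "C4", "C5"),
    n_proteins = c(3000, 2500, 2000, 2000, 1500)),
    class = c("genome_census", "data.frame"))
  md <- data.frame(genome_id = c("C1", "C2", "C3", "C4", "C5"),
                   genus = c("Escherichia", "Escherichia", "Bacillus",
                             "Bacillus", "Vibrio"))
  kept <- select_cellular_representatives(cen, md)
  expect_setequal(kept, c("C1", "C3", "C5"))  # tie at 2000 -> C3 < C4
  md$genus[5] <- ""
  expect_warning(kept2 <- select_cellular_representatives(cen, md),
                 "without genus")
  expect_true("C5" %in% kept2)
})
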