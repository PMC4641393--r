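toy_census <- function(fracs, n_proteins = 100) {
  structure(data.frame(genome_id = sprintf("V%02d", seq_along(fracs)),
                       n_proteins = n_proteins, n_tm = round(fracs * 100),
                       tm_fraction = fracs, stringsAsFactors = FALSE),
            class = c("genome_census", "data.frame"))
}

toy_meta <- function(lipid) {
  data.frame(genome_id = sprintf("V%02d", seq_along(lipid)),
             name = "v", entity_class = "virus", virus_family = "F",
             host_domain = ifelse(lipid, "Archaea", "Bacteria"),
             lipid_class = ifelse(lipid, "lipid_associated", "non_lipid"),
             genus = "g", stringsAsFactors = FALSE)
}

test_that("lipid correlation equals the closed-form point-biserial value", {
  fr <- c(0.3, 0.3, 0.3, 0.05, 0.05, 0.05)
  lipid <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  got <- tm_correlate(toy_census(fr), toy_meta(lipid), "lipid_binary")
  # point-biserial: (m1 - m0)/s * sqrt(p*q), population-sd form via cor()
  expect_equal(got, stats::cor(fr, as.numeric(lipid)))
  expect_equal(got, 1)  # perfectly separated, equal groups
  fr2 <- c(0.35, 0.28, 0.31, 0.04, 0.09, 0.03)
  m1 <- mean(fr2[lipid]); m0 <- mean(fr2[!lipid])
  s <- sqrt(sum((fr2 - mean(fr2))^2) / (length(fr2) - 1))
  rpb <- (m1 - m0) / s * sqrt(0.5 * 0.5 * 6 / 5)
  expect_equal(tm_correlate(toy_census(fr2), toy_meta(lipid),
                            "lipid_binary"), rpb)
})

test_that("correlation errors on zero variance and is affine invariant", {
  expect_error(tm_correlate(toy_census(rep(0.1, 5)), toy_meta(rep(c(TRUE,
    FALSE), length.out = 5)), "lipid_binary"), "zero variance")
  expect_error(tm_correlate(toy_census(c(0.1, 0.2)), toy_meta(c(TRUE,
    FALSE)), "lipid_binary"), "at least 3")
  fr <- c(0.02, 0.31, 0.11, 0.27, 0.08)
  cen <- toy_census(fr); md <- toy_meta(c(FALSE, TRUE, FALSE, TRUE, FALSE))
  cen$n_proteins <- c(50, 300, 120, 80, 400)
  r1 <- tm_correlate(cen, md, "n_proteins")
  cen2 <- cen; cen2$n_proteins <- 7 * cen$n_proteins + 13
  expect_equal(tm_correlate(cen2, md, "n_proteins"), r1)
  expect_equal(sign(r1), sign(stats::cor(fr, cen$n_proteins)))
})

test_that("archaeal host domain codes as 1 for the point-biserial sign", {
  fr <- c(0.30, 0.28, 0.05, 0.06, 0.04)
  md <- toy_meta(c(TRUE, TRUE, FALSE, FALSE, FALSE))  # archaea TM-rich
  expect_gt(tm_correlate(toy_census(fr), md, "host_domain_binary"), 0)
})

test_that("MWW matches its printed small-sample anchors", {
  expect_equal(mww_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- mww_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)
  expect_error(mww_test(numeric(0), 1), "non-empty")
})

test_that("MWW exact p equals full enumeration for every n+m <= 8", {
  set.seed(19)
  sizes <- list(c(1, 2), c(2, 2), c(2, 3), c(3, 3), c(3, 4), c(4, 4),
                c(1, 7), c(2, 6))
  for (sz in sizes) {
    for (rep in 1:6) {
      # half the cases tied by rounding to integers
      x <- stats::runif(sz[1], 0, 4); y <- stats::runif(sz[2], 0, 4)
      if (rep %% 2 == 0) { x <- round(x); y <- round(y) }
      expect_equal(mww_test(x, y)$p_value, oracle_mww_p(x, y),
                   tolerance = 1e-12,
                   label = paste("n,m =", sz[1], sz[2], "rep", rep))
    }
  }
})

test_that("MWW detects a shift with growing power", {
  set.seed(4)
  p_small <- mww_test(rnorm(8), rnorm(8) + 2)$p_value
  p_big <- mww_test(rnorm(60), rnorm(60) + 2)$p_value
  expect_lt(p_big, 1e-10)
  expect_lt(p_big, p_small)
})

test_that("chi-squared histogram test matches the hand Pearson formula", {
  h <- c("0" = 10, "1" = 5, "2" = 5)
  r0 <- chisq_hist_test(h, h)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  tab <- rbind(c(10, 0), c(0, 10))
  r <- chisq_hist_test(tab)
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)
  expect_equal(r$statistic, oracle_pearson_chisq(tab))

  a <- c("0" = 40, "1" = 30, "2" = 20, "3" = 10)
  b <- c("0" = 25, "1" = 25, "2" = 25, "3" = 25)
  r2 <- chisq_hist_test(a, b)
  expect_equal(r2$statistic, oracle_pearson_chisq(rbind(a, b)))
  expect_equal(r2$df, 3)
})

test_that("low-expected bins merge rightward before the chi-squared", {
  a <- c("0" = 50, "1" = 30, "2" = 3, "3" = 1)
  b <- c("0" = 45, "1" = 35, "2" = 2, "3" = 2)
  r <- chisq_hist_test(a, b)
  # bins 2 and 3 merge rightward; the pooled tail bin still expects < 5, so
  # it folds into bin 1, leaving a 2 x 2 table
  expect_equal(r$n_bins_used, 2)
  merged <- rbind(c(50, 34), c(45, 39))
  expect_equal(r$statistic, oracle_pearson_chisq(merged))
  expect_error(chisq_hist_test(c("0" = 1), c("0" = 2)), "fewer than 2")
})

test_that("same-source amino-acid compositions rarely reject under chi-squared", {
  comp <- tmcensus:::soluble_composition()
  set.seed(29)
  p <- replicate(200, {
    a <- as.vector(stats::rmultinom(1, 400, comp))
    b <- as.vector(stats::rmultinom(1, 400, comp))
    names(a) <- names(b) <- names(comp)
    chisq_hist_test(a, b)$p_value
  })
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("orthogroup consistency scores uniformity and discordance size", {
  preds <- make_count_predictions(paste0("p", 1:9),
                                  c(2, 2, 2, 1, 1, 1, 2, 3, 5))
  og <- data.frame(protein_id = paste0("p", 1:9),
                   group_id = c("A", "A", "A", "B", "B", "C", "C", "D", "D"))
  rep <- orthogroup_consistency(preds, og)
  expect_equal(rep$fraction_uniform, 0.5)  # A and B uniform, C and D not
  expect_equal(rep$frac_discordant_by1, 0.5)
  expect_equal(rep$frac_discordant_by2, 0.5)

  # the hand-counted trio: counts {1,1}, {1,2}, {3,5}
  preds2 <- make_count_predictions(paste0("q", 1:6), c(1, 1, 1, 2, 3, 5))
  og2 <- data.frame(protein_id = paste0("q", 1:6),
                    group_id = c("A", "A", "B", "B", "C", "C"))
  rep2 <- orthogroup_consistency(preds2, og2)
  expect_equal(rep2$fraction_uniform, 1 / 3)
  expect_equal(rep2$frac_discordant_by1, 0.5)
  expect_equal(rep2$frac_discordant_by2, 0.5)
})

test_that("consistency fractions ignore member order and singleton groups", {
  counts <- c(2, 2, 2, 1, 3, 0)
  og <- data.frame(protein_id = paste0("p", 1:6),
                   group_id = c("A", "A", "A", "B", "B", "S"))
  base <- orthogroup_consistency(
    make_count_predictions(paste0("p", 1:6), counts), og)
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(6)
    shuf <- orthogroup_consistency(
      make_count_predictions(paste0("p", perm), counts[perm]), og)
    expect_equal(shuf$fraction_uniform, base$fraction_uniform)
    expect_equal(shuf$frac_discordant_by1, base$frac_discordant_by1)
  }
  expect_error(orthogroup_consistency(
    make_count_predictions("p1", 1),
    data.frame(protein_id = "p1", group_id = "A")), "at least 2")
})

test_that("perturbed homolog groups predict uniformly", {
  spec <- synthetic_spec(seed = 3)
  set.seed(14)
  groups <- lapply(1:10, function(i) {
    k <- sample(1:3, 1)
    anc <- tmcensus:::make_tm_protein(k, spec, FALSE)
    copies <- perturb_orthogroup(anc$sequence, anc$segments, n_copies = 4,
                                 indel_rate = 0.01, seed = 100 + i)
    vapply(copies, function(cp) predict_topology(cp$sequence)$n_tm, 0L)
  })
  uniform <- vapply(groups, function(k) length(unique(k)) == 1, TRUE)
  expect_gte(mean(uniform), 0.9)
})
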