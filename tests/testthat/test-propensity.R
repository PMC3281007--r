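aa_cat <- pattern_catalog("aa")

frequency_of_pattern_test <- function(group) {
  vapply(group, function(s) pattern_frequencies(s, aa_cat)["P"], numeric(1),
         USE.NAMES = FALSE)
}

test_that("segment extraction follows the cleavage-point convention", {
  seq10 <- "ACDEFGHIKL"
  seg <- extract_segments(seq10, sites = 5, k = 3)[[1]]
  expect_equal(seg$positions, 2:7)             # site-k .. site+k-1
  expect_equal(paste(seg$symbols, collapse = ""), "CDEFGH")
  # near-terminal sites truncate, not drop
  seg2 <- extract_segments(seq10, sites = 2, k = 3)[[1]]
  expect_equal(seg2$positions, 1:4)
  # k = 10 reproduces the wide representative window
  seg3 <- extract_segments(paste(rep("A", 40), collapse = ""),
                           sites = 20, k = 10)[[1]]
  expect_equal(length(seg3$positions), 20L)
  expect_equal(seg3$positions, 10:29)
  expect_error(extract_segments(seq10, sites = 1, k = 3), "out of range")
  expect_error(extract_segments(seq10, sites = 11, k = 3), "out of range")
})

test_that("pattern frequencies count singles, pairs and classes correctly", {
  f <- pattern_frequencies("PPGG", aa_cat)
  expect_equal(unname(f["P"]), 0.5)
  expect_equal(unname(f["G"]), 0.5)
  expect_equal(sum(f), 1)

  di <- pattern_catalog("sse8", pair_gap = 1)
  f2 <- pattern_frequencies("HHEE", di)
  expect_equal(unname(f2[c("HH", "HE", "EE")]), rep(1 / 3, 3))

  c3 <- pattern_catalog("class3")
  f3 <- pattern_frequencies("LDGA", c3)
  expect_equal(unname(f3["o"]), 0.5)   # L, A hydrophobic
  expect_equal(unname(f3["i"]), 0.25)  # D hydrophilic
  expect_equal(unname(f3["n"]), 0.25)  # G neutral

  # gapped pairs: (s_i, s_{i+2}) over length - 2 positions
  g2 <- pattern_catalog("aa", pair_gap = 2)
  f4 <- pattern_frequencies("PGPG", g2)
  expect_equal(unname(f4["PP"]), 0.5)
  expect_equal(unname(f4["GG"]), 0.5)

  # too short for the pattern: all zero
  expect_true(all(pattern_frequencies("H", di) == 0))
})

test_that("bootstrap aggregating reproduces degenerate and analytic cases", {
  # identical polypeptides: zero bootstrap spread
  b <- bootstrap_mean_occurrence(rep("PPGG", 12), aa_cat, m = 200, seed = 1)
  expect_true(all(b$sd == 0))
  expect_equal(unname(b$mean["P"]), 0.5)

  # bootstrap sd tracks the analytic standard error of the mean
  grp <- generate_sequence_groups(c(), n_seqs = 200, site_length = 30,
                                  background_length = 30, seed = 2)$background
  fmat <- t(vapply(grp, pattern_frequencies, numeric(20), catalog = aa_cat,
                   USE.NAMES = FALSE))
  analytic <- apply(fmat, 2, sd) / sqrt(nrow(fmat))
  b2 <- bootstrap_mean_occurrence(grp, aa_cat, m = 5000, seed = 3)
  rel <- abs(b2$sd - analytic) / analytic
  expect_true(all(rel < 0.15))
})

test_that("permutation test matches exhaustive enumeration and ties give p = 1", {
  # identical groups: every relabeling ties the observed statistic
  res <- permutation_test(rep("PP", 3), rep("PP", 3), "P", aa_cat, T = 99)
  expect_equal(res$p, 1)

  # {1,1,1} vs {0,0,0} frequencies: enumeration over C(6,3) = 20
  g_e <- rep("PP", 3); g_c <- rep("GG", 3)
  res2 <- permutation_test(g_e, g_c, "P", aa_cat, T = 99)
  expect_equal(res2$method, "exact")
  expect_equal(res2$n_resamples, 20L)
  # oracle: enumerate relabelings directly
  v <- c(1, 1, 1, 0, 0, 0)
  stats <- apply(utils::combn(6, 3), 2,
                 function(idx) mean(v[idx]) - mean(v[-idx]))
  expect_equal(res2$p, mean(abs(stats) >= abs(res2$theta_hat) - 1e-12))
  expect_equal(res2$p, 2 / 20)

  # sampling agrees with enumeration within Monte Carlo error
  set.seed(4)
  g_e2 <- replicate(5, paste(sample(c("P", "G"), 4, TRUE), collapse = ""))
  g_c2 <- replicate(5, paste(sample(c("P", "G"), 4, TRUE), collapse = ""))
  exact <- permutation_test(g_e2, g_c2, "P", aa_cat, T = 99)
  samp <- permutation_test(g_e2, g_c2, "P", aa_cat, T = 4999,
                           exact_limit = 1)
  mc_se <- sqrt(exact$p * (1 - exact$p) / 4999)
  expect_lt(abs(samp$p - exact$p), 2 * mc_se + 1 / 5000)
})

test_that("propensity scores follow the significance-weighted log-ratio", {
  expect_equal(propensity_score(0.3, 0.3, 0.01, 0.01), 0)   # equal freqs
  expect_equal(propensity_score(0.5, 0.1, 1, 0.01), 0)      # p = 1, W = 0
  expect_equal(propensity_score(0.04, 0.02, 0.001, 0.01),
               (1 - 0.001) * log2(0.05 / 0.03))
  expect_error(propensity_score(0.1, 0.1, 0.5, 0), "positive")
  # antisymmetric under swapping the groups at fixed p and epsilon
  s1 <- propensity_score(0.04, 0.02, 0.2, 0.01)
  s2 <- propensity_score(0.02, 0.04, 0.2, 0.01)
  expect_equal(s1, -s2)
  expect_gt(s1, 0)
})

test_that("epsilon uses the nonzero-minimum frequencies with a length fallback", {
  g_e <- c("PPGG", "PGGG")  # P freqs 0.5, 0.25 -> min nonzero 0.25
  g_c <- c("GGGG", "PPPG")  # P freqs 0, 0.75 -> min nonzero 0.75
  expect_equal(propensity_epsilon(g_e, g_c, "P", aa_cat), (0.25 + 0.75) / 2)
  # pattern absent from one group: fallback 1 / total length
  g_c2 <- c("GGGG", "GGGG")
  expect_equal(propensity_epsilon(g_e, g_c2, "P", aa_cat),
               (0.25 + 1 / 8) / 2)
})

test_that("score tables cover the catalog and flag enrichment direction", {
  set.seed(5)
  groups <- generate_sequence_groups(c(P = 3), n_seqs = 60, site_length = 8,
                                     background_length = 40, seed = 5)
  tab <- build_score_table(groups$site, groups$background, aa_cat,
                           T = 499, seed = 6)
  expect_s3_class(tab, "cp_propensity")
  expect_setequal(tab$pattern, AA_ALPHABET)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_equal(tab$W, 1 - tab$p)
  p_row <- tab[tab$pattern == "P", ]
  expect_gt(p_row$S_p, 0)     # planted enrichment recovered in sign
  expect_lt(p_row$p, 0.05)
  # S_p = 0 exactly when frequencies agree is enforced by construction
  expect_true(all(sign(tab$S_p) %in% c(sign(tab$f_e - tab$f_c), 0)))
})

test_that("windowed propensity features average the segment scores", {
  st <- build_polypeptide(synthetic_spec(
    blocks = list(c("helix", "10")), seed = 7,
    sequence = "PPPPPPPPPP"))
  tab0 <- data.frame(pattern = AA_ALPHABET, S_p = 0)
  zero <- residue_propensity_features(st, list(aa = tab0), k = 3)
  expect_true(all(zero$R_aa == 0))

  tab <- data.frame(pattern = AA_ALPHABET,
                    S_p = ifelse(AA_ALPHABET == "P", 0.4, 0))
  r <- residue_propensity_features(st, list(aa = tab), k = 3)
  expect_equal(r$R_aa, rep(0.4, 10))  # mean of a constant window

  # terminal windows average only the available symbols
  st2 <- build_polypeptide(synthetic_spec(
    blocks = list(c("helix", "10")), seed = 8,
    sequence = "PGGGGGGGGG"))
  r2 <- residue_propensity_features(st2, list(aa = tab), k = 3)
  expect_equal(r2$R_aa[1], 0.4 / 3)   # window positions 1..3 (truncated)
  expect_equal(r2$R_aa[10], 0)
  # missing symbols score 0 with a warning
  tab_short <- data.frame(pattern = "P", S_p = 0.4)
  expect_warning(
    r3 <- residue_propensity_features(st2, list(aa = tab_short), k = 3),
    "missing")
  expect_equal(r3$R_aa, r2$R_aa)
})

test_that("pattern coverage is the observed fraction of possible combinations", {
  expect_equal(pattern_coverage(character(0), aa_cat), 0)
  # every symbol of a single-symbol catalog observed: 100%
  expect_equal(pattern_coverage(paste(AA_ALPHABET, collapse = ""), aa_cat), 1)
  # 300 distinct di-residue combinations of 400 possible: exactly 75%
  di <- pattern_catalog("aa", pair_gap = 1)
  all_pairs <- as.vector(outer(AA_ALPHABET, AA_ALPHABET, paste0))
  segs <- all_pairs[1:300]
  expect_equal(pattern_coverage(segs, di), 0.75)
})

test_that("propensity score recovers a planted proline enrichment", {
  hits <- 0L
  for (rep_i in 1:5) {
    groups <- generate_sequence_groups(c(P = 1.32), n_seqs = 400,
                                       site_length = 6,
                                       background_length = 120,
                                       seed = 100 + rep_i)
    res <- permutation_test(groups$site, groups$background, "P", aa_cat,
                            T = 999, seed = rep_i)
    eps <- propensity_epsilon(groups$site, groups$background, "P", aa_cat)
    f_e <- mean(frequency_of_pattern_test(groups$site))
    f_c <- mean(frequency_of_pattern_test(groups$background))
    sp <- propensity_score(f_e, f_c, res$p, eps)
    if (res$p < 0.05 && sp > 0) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

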