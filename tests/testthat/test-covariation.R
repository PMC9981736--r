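# MI-APC coupling scores, substitution tables, charge reversal, and the
# coupling-vs-distance agreement analysis

# independent oracle: direct-summation MI over observed pairs (unweighted,
# no pseudocount), kept deliberately separate from the package path
mi_oracle <- function(mat, i, j) {
  ri <- mat[, i]; rj <- mat[, j]
  ok <- ri != "-" & rj != "-"
  tab <- table(ri[ok], rj[ok]) / sum(ok)
  pi_ <- rowSums(tab); pj <- colSums(tab)
  s <- 0
  for (a in rownames(tab)) for (b in colnames(tab))
    if (tab[a, b] > 0) s <- s + tab[a, b] * log2(tab[a, b] / (pi_[a] * pj[b]))
  as.numeric(s)
}

test_that("MI agrees with the direct-summation oracle to 1e-10", {
  aln <- simulate_msa(seed = 3, n_seq = 50, n_col = 10)
  cv <- covariation_scores(aln, weights = rep(1, 50), pseudocount = 0,
                           min_n_eff = 10)
  for (i in c(1, 4)) for (j in c(7, 10)) {
    ki <- match(i, cv$columns); kj <- match(j, cv$columns)
    if (is.na(ki) || is.na(kj)) next
    expect_equal(cv$mi[ki, kj], mi_oracle(aln$mat, i, j), tolerance = 1e-10)
  }
  # symmetry and non-negativity of raw MI
  expect_equal(cv$mi, t(cv$mi), tolerance = 1e-14)
  expect_true(all(cv$mi >= -1e-12))
})

test_that("a perfectly coupled two-state pair attains the top score", {
  aln <- simulate_msa(seed = 5, n_seq = 400, n_col = 40,
                      couplings = list(list(i = 8, j = 31,
                                            states = list(c("R", "E"),
                                                          c("E", "R")),
                                            probs = c(0.5, 0.5))))
  cv <- covariation_scores(aln, weights = rep(1, 400))
  tc <- top_couplings(cv, threshold = -Inf)
  expect_equal(unlist(tc[1, c("col_i", "col_j")], use.names = FALSE), c(8, 31))
  # APC preserves the rank of the single dominant coupling
  mx <- which(cv$apc == max(cv$apc), arr.ind = TRUE)[1, ]
  expect_equal(sort(cv$columns[mx]), c(8, 31))
})

test_that("null alignments stay under the peak threshold", {
  aln <- simulate_msa(seed = 9, n_seq = 1000, n_col = 30)
  cv <- covariation_scores(aln, weights = rep(1, 1000))
  expect_lt(max(cv$z), 4.5)   # no planted pair: nothing stands far out
  # effective-N floor refuses tiny alignments
  tiny <- simulate_msa(seed = 9, n_seq = 5, n_col = 10)
  expect_error(covariation_scores(tiny, weights = rep(1, 5)), "floor")
})

test_that("substitution tables reproduce the generating joint distribution", {
  # degenerate case: always (A, A)
  aln1 <- new_alignment(stats::setNames(rep("AAAA", 30), paste0("s", 1:30)))
  t1 <- pair_substitution_table(aln1, 1, 3)
  expect_equal(t1$joint["A", "A"], 30)
  expect_equal(sum(t1$joint), t1$n_effective)
  # 50/50 RE/ER: two equal off-diagonal cells
  aln2 <- simulate_msa(seed = 15, n_seq = 600, n_col = 12,
                       couplings = list(list(i = 2, j = 9,
                                             states = list(c("R", "E"),
                                                           c("E", "R")),
                                             probs = c(0.5, 0.5))))
  t2 <- pair_substitution_table(aln2, 2, 9)
  expect_equal(sum(t2$joint[c("R", "E"), c("R", "E")]), 600)
  expect_equal(t2$joint["R", "E"] / 600, 0.5, tolerance = 0.08)
  expect_equal(t2$marginal_i, rowSums(t2$joint))
  # chi-square goodness of fit against the generating 50/50 joint
  obs <- c(t2$joint["R", "E"], t2$joint["E", "R"])
  expect_gt(stats::chisq.test(obs, p = c(0.5, 0.5))$p.value, 0.01)
})

test_that("charge-reversal fractions and balance are computed correctly", {
  mk <- function(p_re) simulate_msa(seed = 77, n_seq = 1000, n_col = 6,
    couplings = list(list(i = 1, j = 4,
                          states = list(c("R", "E"), c("E", "R")),
                          probs = c(p_re, 1 - p_re))))
  # all (R, E): balance 0
  t_all <- pair_substitution_table(mk(1), 1, 4)
  f <- charge_reversal_fraction(t_all)
  expect_equal(f$f_plus_minus, 1)
  expect_equal(f$balance, 0)
  # 50/50: balance 1 (within sampling error)
  f50 <- charge_reversal_fraction(pair_substitution_table(mk(0.5), 1, 4))
  expect_gt(f50$balance, 0.85)
  # 60/40 mix: balance ~ 2/3
  f64 <- charge_reversal_fraction(pair_substitution_table(mk(0.6), 1, 4))
  expect_equal(f64$balance, 2 / 3, tolerance = 0.12)
  expect_warning(
    charge_reversal_fraction(list(joint = matrix(0, 20, 20,
                                                 dimnames = list(phosphorelay:::AA20,
                                                                 phosphorelay:::AA20)),
                                  n_effective = 0)),
    "empty")
})

test_that("coupling-vs-distance precision is exact on constructed fixtures", {
  contacts <- data.frame(resseq_a = c(10, 12), resseq_b = c(110, 112),
                         distance = c(4.5, 7.0))
  # all peaks at true tight contacts: precision(<6) = 1
  peaks_hit <- data.frame(number_i = 10, number_j = 110, z = 5)
  rep1 <- covariation_vs_distance(peaks_hit, contacts)
  expect_equal(rep1$precision_tight, 1.0)
  expect_equal(rep1$precision_loose, 1.0)
  # all peaks at non-contacts: precision 0
  peaks_miss <- data.frame(number_i = c(10, 11), number_j = c(111, 115),
                           z = c(4, 6))
  rep0 <- covariation_vs_distance(peaks_miss, contacts)
  expect_equal(rep0$precision_tight, 0.0)
  expect_equal(rep0$precision_loose, 0.0)
  # black-class peak sits between tight and loose
  peaks_mid <- data.frame(number_i = 12, number_j = 112, z = 4)
  repm <- covariation_vs_distance(peaks_mid, contacts)
  expect_equal(repm$pairs$class, "black")
  # no pair above threshold: empty report, precision flagged undefined
  none <- covariation_vs_distance(peaks_mid, contacts, score_threshold = 10)
  expect_equal(nrow(none$pairs), 0)
  expect_true(is.na(none$precision_tight))
  # region filter restricts the axes
  repr <- covariation_vs_distance(peaks_miss, contacts,
                                  region = list(i = c(10, 10),
                                                j = c(100, 120)))
  expect_equal(nrow(repr$pairs), 1)
})

test_that("imported coupling tables run through the same agreement path", {
  p <- write_lines_tmp(c("# i j score", "10 110 4.2", "12 112 3.5",
                         "15 130 3.1"), ext = ".txt")
  tab <- read_coupling_table(p)
  expect_equal(nrow(tab), 3)
  contacts <- data.frame(resseq_a = c(10, 12), resseq_b = c(110, 112),
                         distance = c(4.5, 7.0))
  rep_ <- covariation_vs_distance(tab, contacts)
  expect_equal(sort(rep_$pairs$class), c("black", "miss", "red"))
  expect_equal(rep_$precision_tight, 1 / 3)
  expect_equal(rep_$precision_loose, 2 / 3)
})
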