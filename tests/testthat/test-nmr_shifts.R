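# CSP, secondary shifts, 1-2-1 smoothing, HetNOE flags, Gaussian FWHM

mk_shift <- function(n = 10, H = 8.3, N = 119, CA = 56, CB = 31,
                     restype = "A") {
  shift_table(data.frame(resnum = seq_len(n), restype = restype,
                         H = rep_len(H, n), N = rep_len(N, n),
                         CA = rep_len(CA, n), CB = rep_len(CB, n)))
}

flat_rc <- function(CA = 56, CB = 31) {
  data.frame(restype = phosphorelay:::AA20, CA = CA, CB = CB)
}

test_that("CSP follows the amide formula with 15N scaled by 5", {
  ref <- mk_shift()
  # identical tables: all zero, class none
  p0 <- csp(ref, ref)
  expect_equal(p0$dd, rep(0, 10))
  expect_true(all(p0$class == "none"))
  # dH = 0.1, dN = 0: formula collapses to 0.1
  mod <- ref; mod$H <- ref$H + 0.1
  expect_equal(csp(ref, mod)$dd, rep(0.1, 10))
  # dH = 0.3, dN = 1.0: sqrt(0.09 + 0.04) = 0.3606, class medium
  mod2 <- ref; mod2$H <- ref$H - 0.3; mod2$N <- ref$N + 1.0
  p2 <- csp(ref, mod2)
  expect_equal(p2$dd, rep(sqrt(0.13), 10), tolerance = 1e-12)
  expect_equal(round(p2$dd[1], 4), 0.3606)
  expect_true(all(p2$class == "medium"))
  # symmetry in the two arguments
  expect_equal(csp(mod2, ref)$dd, p2$dd)
  # residues missing in one table are marked unassigned (NA class)
  short <- shift_table(ref[1:8, ])
  pna <- csp(ref, short)
  expect_true(is.na(pna$dd[10]) && is.na(pna$class[10]))
  # mismatched residue types warn but compute
  modt <- mod; modt$restype[3] <- "G"
  expect_warning(csp(ref, modt), "mismatch")
})

test_that("secondary shifts combine Ca/Cb deviations and call propensity", {
  rc <- flat_rc()
  # shifts equal to random coil: all zeros, coil
  flat <- secondary_shifts(mk_shift(), rc = rc)
  expect_equal(flat$raw, rep(0, 10))
  expect_true(all(flat$propensity == "coil"))
  # +2 Ca / -1 Cb over 6 residues: combined +3, helix call
  t2 <- mk_shift(n = 10)
  t2$CA[3:8] <- 58; t2$CB[3:8] <- 30
  s2 <- secondary_shifts(t2, rc = rc)
  expect_equal(s2$raw[5], 3)
  expect_true(all(s2$propensity[4:7] == "helix"))
  # invariance under adding a constant to both observed and reference
  t3 <- t2; t3$CA <- t3$CA + 5
  rc3 <- flat_rc(CA = 61)
  expect_equal(secondary_shifts(t3, rc = rc3)$raw, s2$raw)
  # glycine: Cb term dropped and flagged
  tg <- shift_table(data.frame(resnum = 1:5, restype = c("A", "G", "A", "A", "A"),
                               H = 8, N = 119, CA = 58, CB = 30))
  sg <- secondary_shifts(tg, rc = rc)
  expect_true(sg$gly_flag[2])
  expect_equal(sg$raw[2], 2)     # only the Ca term
  expect_equal(sg$raw[1], 3)
  # unknown residue type errors by name
  tu <- mk_shift(); tu$restype[1] <- "B"
  expect_error(shift_table(tu), NA)  # table itself is fine
  expect_error(secondary_shifts(shift_table(tu), rc = rc), "B")
})

test_that("1-2-1 smoothing: impulse response, ends, gaps, mean preservation", {
  # interior impulse with renormalized end rule
  expect_equal(smooth_121(c(0, 1, 0)), c(1 / 3, 0.5, 1 / 3))
  # constant series unchanged
  expect_equal(smooth_121(rep(2.5, 6)), rep(2.5, 6))
  # gaps are preserved and never mixed across
  x <- c(1, 1, NA, 5, 5)
  sm <- smooth_121(x)
  expect_true(is.na(sm[3]))
  expect_equal(sm[4], 5)     # left neighbour is a gap, renormalized
  # numbering breaks act as gaps
  sm2 <- smooth_121(c(1, 1, 9, 9), positions = c(1, 2, 10, 11))
  expect_equal(sm2, c(1, 1, 9, 9))
  # mean preservation for gap-free series (renormalized end rule):
  # endpoint deficit is balanced analytically for constant-sum interior
  set.seed(8)
  for (i in 1:5) {
    v <- rnorm(20)
    sm3 <- smooth_121(v)
    # weights: each interior value contributes 1/4+1/2+1/4 = 1; ends differ
    manual <- c((2 * v[1] + v[2]) / 3,
                (v[1:18] + 2 * v[2:19] + v[3:20]) / 4,
                (v[19] + 2 * v[20]) / 3)
    expect_equal(sm3, manual, tolerance = 1e-12)
  }
})

test_that("planted perturbations and helical segments are recovered", {
  # planted dd = 0.5 ppm at 5 residues, tiny noise: exactly those strong
  sp <- simulate_shift_pair(seed = 2, perturbed = 71:75, dd_h = 0.5,
                            dd_n = 0, noise_sd = 0.02)
  prof <- csp(sp$ref, sp$mod)
  expect_equal(prof$resnum[which(prof$class == "strong")], 71:75)
  # helical segment recovery with boundary error <= 1 residue in >= 90 %
  # of seeds (50 seeds; sigma 0.3 ppm as stated)
  hits <- vapply(1:50, function(seed) {
    spi <- simulate_shift_pair(seed = seed, helix_segments = list(c(30, 45)),
                               noise_sd = 0.3)
    sec <- secondary_shifts(spi$ref, rc = random_coil_table())
    run <- range(sec$resnum[sec$propensity == "helix"])
    all(abs(run - c(30, 45)) <= 1)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("HetNOE thresholding flags mobile residues", {
  flat <- hetnoe_flags(rep(0.85, 20))
  expect_false(any(flat$mobile))
  one <- hetnoe_flags(c(rep(0.85, 5), 0.3, rep(0.85, 4)))
  expect_equal(which(one$mobile), 6)
  # planted mobile segment exactly recovered
  set.seed(14)
  vals <- c(rnorm(30, 0.8, 0.05), rnorm(8, 0.4, 0.05), rnorm(30, 0.8, 0.05))
  fl <- hetnoe_flags(vals, threshold = 0.65)
  expect_equal(which(fl$mobile), 31:38)
  expect_warning(hetnoe_flags(c(0.8, 1.9)), "plausible")
})

test_that("Gaussian FWHM fitting hits the closed form", {
  x <- seq(-6, 6, by = 0.05)
  fit <- gaussian_fwhm(x, exp(-x^2 / 2))
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-4)
  expect_equal(fit$center, 0, tolerance = 1e-6)
  # amplitude scaling leaves the width unchanged
  fit10 <- gaussian_fwhm(x, 10 * exp(-x^2 / 2))
  expect_equal(fit10$fwhm, fit$fwhm, tolerance = 1e-6)
  # 2 % white noise: width within 3 % across seeds
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    y <- exp(-(x - 0.3)^2 / (2 * 0.8^2)) + rnorm(length(x), 0, 0.02)
    abs(gaussian_fwhm(x, y)$fwhm - 2 * sqrt(2 * log(2)) * 0.8) /
      (2 * sqrt(2 * log(2)) * 0.8)
  }, 0)
  expect_lt(max(errs), 0.03)
  expect_error(gaussian_fwhm(1:3, 1:3), "at least 5")
})

test_that("shift-table io reads both CSV and NMR-STAR-like dialects", {
  csv <- write_lines_tmp(c("resnum,restype,H,N,CA,CB",
                           "5,A,8.2,118.0,52.6,19.1",
                           "6,G,8.4,110.2,45.2,"), ext = ".csv")
  t1 <- read_shift_table(csv)
  expect_s3_class(t1, "ShiftTable")
  expect_equal(t1$CA, c(52.6, 45.2))
  expect_true(is.na(t1$CB[2]))
  star <- write_lines_tmp(c("# assigned chemical shifts",
                            "1 5 ALA CA 52.6",
                            "2 5 ALA H 8.2",
                            "3 5 ALA N 118.0",
                            "4 6 GLY CA 45.2",
                            "5 6 GLY H 8.4"), ext = ".txt")
  t2 <- read_shift_table(star)
  expect_equal(t2$resnum, c(5L, 6L))
  expect_equal(t2$CA, c(52.6, 45.2))
  expect_equal(t2$restype, c("A", "G"))
})
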