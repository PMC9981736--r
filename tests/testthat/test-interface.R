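# residue contacts, Shrake-Rupley SASA, interface area, crystal contacts,
# salt bridges

test_that("residue contacts flag tight/loose membership correctly", {
  A <- atom_df(c(0, 0, 0), resseq = 1)
  B5 <- atom_df(c(5, 0, 0), chain = "B", resseq = 10)
  B100 <- atom_df(c(100, 0, 0), chain = "B", resseq = 11)
  far <- residue_contacts(A, B100)
  expect_equal(nrow(far), 0)
  cs <- residue_contacts(A, rbind(B5, B100))
  expect_equal(nrow(cs), 1)
  expect_equal(cs$distance, 5)
  expect_true(cs$tight)
  # at tight == loose the set reduces to direct single-threshold enumeration
  sc <- make_graft_scenario(seed = 12)
  at <- select_atoms(sc$template)
  ga <- at[at$chain == "A", ]; gb <- at[at$chain == "B", ]
  cs2 <- residue_contacts(ga, gb, loose = 6, tight = 6)
  d <- sqrt(phosphorelay:::cross_dist2(ga[, c("x", "y", "z")],
                                       gb[, c("x", "y", "z")]))
  brute <- unique(data.frame(
    a = ga$resseq[row(d)[d <= 6]], b = gb$resseq[col(d)[d <= 6]]))
  expect_equal(nrow(cs2), nrow(brute))
  expect_true(all(cs2$tight))
})

test_that("SASA matches closed forms for isolated and overlapping spheres", {
  one <- atom_df(c(0, 0, 0), element = "C")
  a1 <- shrake_rupley_sasa(one, probe = 1.4, n_points = 960)
  exact <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(a1 - exact) / exact, 0.01)
  # two identical atoms far apart: each equals the isolated value
  two_far <- rbind(atom_df(c(0, 0, 0), element = "C"),
                   atom_df(c(50, 0, 0), chain = "B", element = "C"))
  a2 <- shrake_rupley_sasa(two_far, n_points = 960)
  expect_equal(a2, rep(a1, 2), tolerance = 1e-9)
  # two overlapping spheres at distance d: analytic spherical-cap area
  # accessible area per sphere = 4 pi R^2 - 2 pi R h, h = R - d/2 (equal R)
  d <- 3.0; R <- 1.70 + 1.4
  two_close <- rbind(atom_df(c(0, 0, 0), element = "C"),
                     atom_df(c(d, 0, 0), chain = "B", element = "C"))
  a3 <- shrake_rupley_sasa(two_close, n_points = 960)
  analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_lt(max(abs(a3 - analytic)) / analytic, 0.02)
  # unknown element falls back with a warning
  weird <- atom_df(c(0, 0, 0), element = "XX")
  expect_warning(shrake_rupley_sasa(weird), "unknown element")
  expect_error(shrake_rupley_sasa(one, n_points = 50), ">= 92")
})

test_that("SASA monotonicity and sampling convergence hold", {
  sc <- make_graft_scenario(seed = 5)
  at <- select_atoms(sc$template)
  base <- shrake_rupley_sasa(at, n_points = 240)
  # adding an atom never increases any existing atom's SASA
  new_row <- at[1, ]
  new_row[, c("x", "y", "z")] <- colMeans(at[, c("x", "y", "z")]) + c(2, 0, 0)
  new_row$chain <- "Z"; new_row$resseq <- 999L
  extra <- rbind(at, new_row)
  more <- shrake_rupley_sasa(extra, n_points = 240)
  expect_true(all(more[seq_len(nrow(at))] <= base + 1e-9))
  # doubling the point count changes the total by < 0.5 %
  tot1 <- sum(shrake_rupley_sasa(at, n_points = 480))
  tot2 <- sum(shrake_rupley_sasa(at, n_points = 960))
  expect_lt(abs(tot1 - tot2) / tot2, 0.005)
})

test_that("interface area obeys its definitional identity and symmetry", {
  sc <- make_graft_scenario(seed = 5)
  at <- select_atoms(sc$template)
  A <- at[at$chain == "A", ]; B <- at[at$chain == "B", ]
  rep_ab <- interface_area(sc$template, "A", "B", n_points = 480)
  # definitional oracle: recompute from the three SASA calls directly
  sA <- sum(shrake_rupley_sasa(A, n_points = 480))
  sB <- sum(shrake_rupley_sasa(B, n_points = 480))
  sAB <- sum(shrake_rupley_sasa(rbind(A, B), n_points = 480))
  expect_equal(rep_ab$area, (sA + sB - sAB) / 2, tolerance = 1e-6)
  expect_gt(rep_ab$area, 0)  # the helices are in contact
  # swapping the groups leaves the two-side average unchanged
  rep_ba <- interface_area(sc$template, "B", "A", n_points = 480)
  expect_equal(rep_ba$area, rep_ab$area, tolerance = 1e-9)
  # far-apart groups: zero area
  Bfar <- B; Bfar$x <- Bfar$x + 200
  rep_far <- interface_area(sc$template, A, Bfar, n_points = 240)
  expect_equal(rep_far$area, 0, tolerance = 1e-9)
})

test_that("crystal contact scan finds exactly the touching mates", {
  # toy crystal: helix in a cell chosen so copies touch along a only
  h <- make_helix_domain(8)
  span_x <- diff(range(h$atoms$x))
  a_len <- span_x + 1
  s <- new_structure(h$atoms[, 1:12],
                     cell = c(a_len, 60, 60, 90, 90, 90),
                     spacegroup = "P 1", id = "toyxtal")
  # radius chosen just above the actual copy-copy approach distance
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  gap <- phosphorelay:::min_cross_dist(xyz, sweep(xyz, 2, c(a_len, 0, 0), "+"))
  scan <- crystal_contact_scan(s, radius = gap + 1, n_points = 240)
  expect_true(length(scan) >= 1)
  areas <- vapply(scan, function(e) e$report$area, 0)
  expect_true(all(diff(areas) <= 1e-9))      # sorted descending
  expect_gt(areas[1], 0)
  # single atom in a huge P1 cell: no burial anywhere
  lone <- new_structure(atom_df(c(0, 0, 0), element = "C"),
                        cell = c(60, 60, 60, 90, 90, 90), spacegroup = "P 1")
  scan0 <- crystal_contact_scan(lone, radius = 5, n_points = 240)
  expect_true(all(vapply(scan0, function(e) e$report$area, 0) < 1e-9))
})

test_that("salt bridges are detected by residue class and O-N distance", {
  asp_o <- atom_df(c(0, 0, 0), resseq = 580, resname = "ASP", atom = "OD1",
                   element = "O")
  arg_n <- atom_df(c(2.8, 0, 0), resseq = 593, resname = "ARG", atom = "NH1",
                   element = "N")
  lys_far <- atom_df(c(5.0, 0, 0), resseq = 600, resname = "LYS", atom = "NZ",
                     element = "N")
  s <- new_structure(rbind(asp_o, arg_n, lys_far))
  sb <- detect_salt_bridges(s, cutoff = 4.0)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$resseq_acid, 580)
  expect_equal(sb$resseq_base, 593)
  expect_equal(sb$distance, 2.8)
  # beyond cutoff: not detected
  expect_equal(nrow(detect_salt_bridges(s, cutoff = 2.0)), 0)
  # inter-chain scope excludes the intra-chain pair
  expect_equal(nrow(detect_salt_bridges(s, scope = "inter-chain")), 0)
  # histidine only counts as basic when asked
  his_n <- atom_df(c(0, 3.0, 0), chain = "B", resseq = 10, resname = "HIS",
                   atom = "NE2", element = "N")
  s2 <- new_structure(rbind(asp_o, his_n))
  expect_equal(nrow(detect_salt_bridges(s2)), 0)
  expect_equal(nrow(detect_salt_bridges(s2, include_his = TRUE)), 1)
})
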