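# template grafting, transfer geometry, inter-domain clash counting

test_that("grafting an unmodified donor is the identity", {
  sc <- make_graft_scenario(seed = 1)
  # donor = template domain itself: transform ~ identity, rmsd 0
  caA <- atom_selection(chains = "A", residue_ranges = c(1, 15),
                        atom_class = "CA")
  tplA <- sc$template
  domA <- new_structure(tplA$atoms[tplA$atoms$chain == "A", 1:12],
                        id = "tplA-copy")
  m <- graft_complex(tplA, list(list(structure = domA,
                                     anchor = anchor_spec(caA, caA))))
  p <- m$provenance[[1]]
  expect_equal(p$anchor_rmsd, 0, tolerance = 1e-9)
  expect_equal(p$transform$rotation, diag(3), tolerance = 1e-7)
  expect_equal(p$transform$translation, c(0, 0, 0), tolerance = 1e-7)
})

test_that("zero-noise scramble recovery reproduces template geometry", {
  for (seed in c(2, 17, 23)) {
    sc <- make_graft_scenario(seed = seed, noise_sd = 0)
    m <- graft_complex(sc$template,
                       list(list(structure = sc$donors$A, anchor = sc$anchors$A),
                            list(structure = sc$donors$B, anchor = sc$anchors$B)))
    caA <- select_atoms(m$assembly, atom_selection(chains = "A",
                                                   atom_class = "CA"))
    caB <- select_atoms(m$assembly, atom_selection(chains = "B",
                                                   atom_class = "CA"))
    dm <- sqrt(phosphorelay:::cross_dist2(caA[, c("x", "y", "z")],
                                          caB[, c("x", "y", "z")]))
    expect_lt(max(abs(dm - sc$truth$interdomain_ca_dist)), 1e-6)
    expect_equal(vapply(m$provenance, function(p) p$anchor_rmsd, 0),
                 c(0, 0), tolerance = 1e-7)
  }
})

test_that("grafting is idempotent and anchor rmsd is re-derivable", {
  sc <- make_graft_scenario(seed = 4, noise_sd = 0.3)
  m <- graft_complex(sc$template,
                     list(list(structure = sc$donors$A, anchor = sc$anchors$A),
                          list(structure = sc$donors$B, anchor = sc$anchors$B)))
  # re-graft the grafted A component: transform must be the identity
  grafted_A <- new_structure(
    m$assembly$atoms[m$assembly$atoms$chain == "A", 1:12], id = "regraft")
  m2 <- graft_complex(sc$template,
                      list(list(structure = grafted_A,
                                anchor = sc$anchors$A)))
  p2 <- m2$provenance[[1]]
  expect_equal(p2$transform$rotation, diag(3), tolerance = 1e-7)
  expect_equal(p2$transform$translation, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(p2$anchor_rmsd, m$provenance[[1]]$anchor_rmsd,
               tolerance = 1e-9)
  # stored anchor rmsd equals an independent kabsch refit
  ca_d <- select_atoms(sc$donors$A, sc$anchors$A$component_selection)
  ca_t <- select_atoms(sc$template, sc$anchors$A$template_selection)
  refit <- kabsch_fit(as.matrix(ca_d[, c("x", "y", "z")]),
                      as.matrix(ca_t[, c("x", "y", "z")]))
  expect_equal(refit$rmsd, m$provenance[[1]]$anchor_rmsd, tolerance = 1e-9)
})

test_that("anchor mismatches error; noisy anchors only warn", {
  sc <- make_graft_scenario(seed = 6)
  bad <- anchor_spec(atom_selection(chains = "A", residue_ranges = c(1, 10),
                                    atom_class = "CA"),
                     atom_selection(chains = "A", residue_ranges = c(1, 15),
                                    atom_class = "CA"))
  expect_error(graft_complex(sc$template,
                             list(list(structure = sc$donors$A, anchor = bad))),
               "resolves to")
  noisy <- make_graft_scenario(seed = 6, noise_sd = 1.2)
  expect_warning(
    graft_complex(noisy$template,
                  list(list(structure = noisy$donors$A,
                            anchor = noisy$anchors$A)),
                  anchor_rmsd_warn = 0.5),
    "above ceiling")
})

test_that("transfer geometry measures named atoms and is rigid-invariant", {
  atoms <- rbind(
    atom_df(c(0, 0, 0), chain = "A", resseq = 322, resname = "HIS",
            atom = "NE2", element = "N"),
    atom_df(c(3, 4, 0), chain = "B", resseq = 623, resname = "ASP",
            atom = "CG", element = "C"),
    atom_df(c(3, 4, 1), chain = "B", resseq = 623, resname = "ASP",
            atom = "OD1", element = "O"))
  s <- new_structure(atoms)
  g <- measure_transfer_geometry(s, list(chain = "A", resseq = 322),
                                 list(chain = "B", resseq = 623))
  expect_equal(g$distance, 5)
  expect_equal(g$distance_min_O, sqrt(26))
  expect_equal(g$convention, "NE2-CG")
  # invariant under a rigid transform of the whole assembly
  set.seed(2)
  s2 <- apply_transform(s, rigid_transform(phosphorelay:::random_rotation(),
                                           rnorm(3, 0, 8)))
  g2 <- measure_transfer_geometry(s2, list(chain = "A", resseq = 322),
                                  list(chain = "B", resseq = 623))
  expect_equal(g2$distance, 5, tolerance = 1e-9)
  expect_error(
    measure_transfer_geometry(s, list(chain = "A", resseq = 322),
                              list(chain = "B", resseq = 999)),
    "not found")
})

test_that("clash counting enumerates exactly the close cross-group pairs", {
  sc <- make_graft_scenario(seed = 8)
  m <- graft_complex(sc$template,
                     list(list(structure = sc$donors$A, anchor = sc$anchors$A),
                          list(structure = sc$donors$B, anchor = sc$anchors$B)))
  # far-apart groups: zero clashes (template helices are in vdW contact,
  # not clashing, at the default mainchain+CB 3.0 A criterion)
  cl <- count_interdomain_clashes(m, "A", "B")
  expect_equal(cl$n_clashes, 0)
  # construct a forced clash and check it is enumerated
  shifted <- m
  shifted$assembly$atoms[shifted$assembly$atoms$chain == "B", c("x", "y", "z")] <-
    shifted$assembly$atoms[shifted$assembly$atoms$chain == "A", c("x", "y", "z")] +
    matrix(rep(c(0.5, 0, 0), each = sum(shifted$assembly$atoms$chain == "A")),
           ncol = 3)
  cl2 <- count_interdomain_clashes(shifted, "A", "B", cutoff = 3.0)
  # brute-force recount
  at <- select_atoms(shifted$assembly,
                     atom_selection(atom_class = "mainchain+CB"))
  A <- at[at$chain == "A", ]; B <- at[at$chain == "B", ]
  d <- sqrt(phosphorelay:::cross_dist2(A[, c("x", "y", "z")],
                                       B[, c("x", "y", "z")]))
  expect_equal(cl2$n_clashes, sum(d < 3.0))
  expect_true(all(cl2$clashes$distance < 3.0))
  expect_error(count_interdomain_clashes(m, "A", "A"), "overlap")
})
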