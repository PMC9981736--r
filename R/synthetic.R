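# Seeded synthetic-data generators: every pipeline stage has a generator
# producing fixtures with the statistical structure that stage assumes, so
# the full analysis chain is testable without any external downloads.

# place atom D given A-B-C with bond |CD|, angle B-C-D and torsion A-B-C-D
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180; tor <- torsion_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build an ideal alpha-helical domain
#'
#' Constructs a poly-alanine (or poly-glycine when `sidechain = "none"`)
#' alpha helix from standard backbone geometry (phi = -57, psi = -47,
#' omega = 180 degrees), giving the canonical ~1.5 Angstrom rise and ~100
#' degree twist per residue and consecutive CA-CA distances of ~3.8
#' Angstrom. Atoms are N, CA, C, O and (optionally) a CB stub.
#'
#' @param n_res number of residues (>= 4).
#' @param chain chain id.
#' @param first_resseq author number of the first residue.
#' @param sidechain `"CB-stub"` (default) or `"none"`.
#' @param phi,psi backbone torsions in degrees (defaults: ideal helix; the
#'   defaults produce rise ~1.5 A and twist ~100 degrees).
#' @param id structure id.
#' @return a `Structure`.
#' @export
make_helix_domain <- function(n_res, chain = "A", first_resseq = 1L,
                              sidechain = c("CB-stub", "none"),
                              phi = -57, psi = -47, id = "helix") {
  sidechain <- match.arg(sidechain)
  stopifnot(n_res >= 4)
  # seed triad for residue 1
  atoms <- list()
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(pi - 111.2 * pi / 180), sin(pi - 111.2 * pi / 180), 0)
  prevN <- N; prevCA <- CA; prevC <- C
  resname <- if (sidechain == "CB-stub") "ALA" else "GLY"
  push <- function(i, at, el, xyz)
    data.frame(chain = chain, resseq = first_resseq + i - 1L, icode = "",
               resname = resname, atom = at, element = el,
               x = xyz[1], y = xyz[2], z = xyz[3], bfactor = 10,
               occupancy = 1, altloc = "", stringsAsFactors = FALSE)
  rows <- list(push(1, "N", "N", N), push(1, "CA", "C", CA),
               push(1, "C", "C", C))
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N2 <- nerf_place(prevN, prevCA, prevC, 1.329, 116.2, psi)
      CA2 <- nerf_place(prevCA, prevC, N2, 1.458, 121.7, 180)
      C2 <- nerf_place(prevC, N2, CA2, 1.525, 111.2, phi)
      rows <- c(rows, list(push(i, "N", "N", N2), push(i, "CA", "C", CA2),
                           push(i, "C", "C", C2)))
      # carbonyl O of the previous residue, anti to the new N
      O <- nerf_place(N2, prevCA, prevC, 1.231, 120.5, 180)
      rows <- c(rows, list(push(i - 1, "O", "O", O)))
      if (sidechain == "CB-stub") {
        CB <- nerf_place(prevC, N2, CA2, 1.521, 110.5, phi + 122.6)
        rows <- c(rows, list(push(i, "CB", "C", CB)))
      }
      prevN <- N2; prevCA <- CA2; prevC <- C2
    } else if (sidechain == "CB-stub") {
      CB <- nerf_place(C, N, CA, 1.521, 110.5, -122.6)
      rows <- c(rows, list(push(1, "CB", "C", CB)))
    }
  }
  # terminal carbonyl O, in the plane of the last peptide unit
  O <- nerf_place(prevN, prevCA, prevC, 1.231, 120.5, psi + 180)
  rows <- c(rows, list(push(n_res, "O", "O", O)))
  a <- do.call(rbind, rows)
  a <- a[order(a$resseq, match(a$atom, c("N", "CA", "C", "O", "CB"))), ]
  new_structure(a, id = id)
}

#' Generate a template-grafting scenario with known ground truth
#'
#' The template is a two-domain complex of ideal helices placed side by side
#' in contact; the donors are copies of each domain, optionally perturbed by
#' isotropic Gaussian coordinate noise, then scrambled by recorded random
#' rigid transforms. Grafting the donors back onto the template must recover
#' the template's inter-domain geometry (exactly at zero noise).
#'
#' @param seed master seed.
#' @param n_res residues per helix domain (default 15).
#' @param separation inter-axis distance in Angstrom (default 9.5, van der
#'   Waals contact for helix pairs).
#' @param noise_sd isotropic coordinate noise sigma in Angstrom (default 0).
#' @return list with `template` (Structure, chains `A` and `B`),
#'   `donors` (list of scrambled donor Structures), `truth` (per-donor
#'   scramble `RigidTransform`s and the template inter-domain CA distance
#'   matrix), and `anchors` (AnchorSpecs covering each full helix).
#' @export
make_graft_scenario <- function(seed = 1, n_res = 15, separation = 9.5,
                                noise_sd = 0) {
  with_scoped_seed(seed, "graft", {
    domA <- make_helix_domain(n_res, chain = "A", id = "domainA")
    domB <- make_helix_domain(n_res, chain = "B", id = "domainB")
    # align each helix roughly along its principal axis, offset domain B
    axis_align <- function(s) {
      ca <- select_atoms(s, atom_selection(atom_class = "CA"))
      xyz <- as.matrix(ca[, c("x", "y", "z")])
      cen <- colMeans(xyz)
      pc <- svd(sweep(xyz, 2, cen))$v
      if (det(pc) < 0) pc[, 3] <- -pc[, 3]
      apply_transform(s, rigid_transform(t(pc), -as.numeric(t(pc) %*% cen)))
    }
    domA <- axis_align(domA)
    domB <- apply_transform(axis_align(domB),
                            rigid_transform(diag(3), c(0, separation, 0)))
    template <- new_structure(rbind(domA$atoms[, 1:12], domB$atoms[, 1:12]),
                              id = "template")
    scramble <- function(s, nm) {
      tf <- rigid_transform(random_rotation(), stats::rnorm(3, 0, 20))
      s2 <- apply_transform(s, tf)
      if (noise_sd > 0) {
        s2$atoms$x <- s2$atoms$x + stats::rnorm(nrow(s2$atoms), 0, noise_sd)
        s2$atoms$y <- s2$atoms$y + stats::rnorm(nrow(s2$atoms), 0, noise_sd)
        s2$atoms$z <- s2$atoms$z + stats::rnorm(nrow(s2$atoms), 0, noise_sd)
      }
      s2$id <- nm
      list(structure = s2, transform = tf)
    }
    scA <- scramble(domA, "donorA"); scB <- scramble(domB, "donorB")
    caA <- select_atoms(domA, atom_selection(atom_class = "CA"))
    caB <- select_atoms(domB, atom_selection(atom_class = "CA"))
    dmat <- sqrt(cross_dist2(caA[, c("x", "y", "z")],
                             caB[, c("x", "y", "z")]))
    rr <- c(1L, n_res)
    anchors <- list(
      A = anchor_spec(
        atom_selection(chains = "A", residue_ranges = rr, atom_class = "CA"),
        atom_selection(chains = "A", residue_ranges = rr, atom_class = "CA"),
        label = "helix A"),
      B = anchor_spec(
        atom_selection(chains = "B", residue_ranges = rr, atom_class = "CA"),
        atom_selection(chains = "B", residue_ranges = rr, atom_class = "CA"),
        label = "helix B"))
    list(template = template,
         donors = list(A = scA$structure, B = scB$structure),
         truth = list(scramble = list(A = scA$transform, B = scB$transform),
                      interdomain_ca_dist = dmat),
         anchors = anchors)
  })
}

#' Simulate a multiple sequence alignment with planted structure
#'
#' Rows are sampled independently; independent columns from per-column
#' profiles, planted coupled column pairs jointly from stated pair
#' distributions (e.g. charge-reversal mixes of an ion pair), and motif
#' columns forced to a consensus pattern with a stated per-position
#' fidelity.
#'
#' @param seed master seed.
#' @param n_seq number of rows (default 500).
#' @param n_col number of columns (default 60).
#' @param profiles optional L x 20 matrix of column distributions; default:
#'   each column concentrates 60 percent on a random residue with the rest
#'   uniform - moderately conserved, like a protein-family core.
#' @param couplings list of planted couplings, each
#'   `list(i =, j =, states = list(c(aa_i, aa_j), ...), probs =, strength =)`:
#'   with probability `strength` the pair is drawn jointly from `states`
#'   (with probabilities `probs`), otherwise independently from the column
#'   profiles.
#' @param motif optional `list(start =, pattern =, fidelity =)`; each row
#'   carries the full motif with probability `fidelity`, otherwise keeps its
#'   background draws.
#' @return an `Alignment` with `attr(, "truth")` recording the generator
#'   configuration.
#' @export
simulate_msa <- function(seed = 1, n_seq = 500, n_col = 60,
                         profiles = NULL, couplings = list(),
                         motif = NULL) {
  with_scoped_seed(seed, "msa", {
    if (is.null(profiles)) {
      profiles <- matrix(0.4 / 19, n_col, 20, dimnames = list(NULL, AA20))
      top <- sample.int(20, n_col, replace = TRUE)
      profiles[cbind(seq_len(n_col), top)] <- 0.6
    }
    stopifnot(nrow(profiles) == n_col,
              all(abs(rowSums(profiles) - 1) < 1e-6))
    mat <- matrix("", n_seq, n_col)
    for (j in seq_len(n_col))
      mat[, j] <- sample(AA20, n_seq, replace = TRUE, prob = profiles[j, ])
    for (cp in couplings) {
      stopifnot(abs(sum(cp$probs) - 1) < 1e-6)
      strength <- cp$strength %||% 1
      coupled <- stats::runif(n_seq) < strength
      pick <- sample.int(length(cp$states), sum(coupled), replace = TRUE,
                         prob = cp$probs)
      st <- do.call(rbind, cp$states)
      mat[coupled, cp$i] <- st[pick, 1]
      mat[coupled, cp$j] <- st[pick, 2]
    }
    if (!is.null(motif)) {
      toks <- motif_tokens(motif$pattern)
      fid <- motif$fidelity %||% 1
      # a row either carries the full motif (probability = fidelity) or
      # keeps its background draws, so window support tracks fidelity
      forced <- stats::runif(n_seq) < fid
      for (k in seq_along(toks)) {
        j <- motif$start + k - 1
        mat[forced, j] <- sample(toks[[k]], sum(forced), replace = TRUE)
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- paste0("seq", seq_len(n_seq))
    out <- new_alignment(seqs)
    attr(out, "truth") <- list(seed = seed, profiles = profiles,
                               couplings = couplings, motif = motif)
    out
  })
}

#' Simulate a reference/modified chemical-shift table pair
#'
#' The reference table is random coil plus planted helical-segment secondary
#' shifts plus noise; the modified table adds a planted amide perturbation
#' at a stated residue set. Ground truth (segments, perturbed set) is
#' attached so recovery can be scored.
#'
#' @param seed master seed.
#' @param n_res chain length (default 120).
#' @param helix_segments list of `c(start, end)` residue ranges carrying
#'   helical secondary shifts (default one segment 30-45).
#' @param helix_offsets `c(dCA, dCB)` secondary-shift offsets inside helical
#'   segments in ppm (default `c(+2.1, -0.9)`, i.e. combined +3.0).
#' @param perturbed integer residue numbers receiving the CSP (default
#'   71:75).
#' @param dd_h,dd_n planted perturbation in ppm on 1H and 15N (defaults 0.45
#'   and 1.0; together they exceed the strong threshold).
#' @param noise_sd carbon-shift noise sigma in ppm (default 0.3; amide noise
#'   is `noise_sd / 10`, reflecting the narrower 1H dispersion).
#' @param rc random-coil table to build on (default: bundled).
#' @return list `ref`, `mod` (ShiftTables), `truth`.
#' @export
simulate_shift_pair <- function(seed = 1, n_res = 120,
                                helix_segments = list(c(30, 45)),
                                helix_offsets = c(2.1, -0.9),
                                perturbed = 71:75,
                                dd_h = 0.45, dd_n = 1.0,
                                noise_sd = 0.3, rc = random_coil_table()) {
  with_scoped_seed(seed, "shifts", {
    types <- sample(setdiff(AA20, "G"), n_res, replace = TRUE)
    idx <- match(types, rc$restype)
    in_helix <- rep(FALSE, n_res)
    for (seg in helix_segments) in_helix[seg[1]:seg[2]] <- TRUE
    ca <- rc$CA[idx] + ifelse(in_helix, helix_offsets[1], 0) +
      stats::rnorm(n_res, 0, noise_sd)
    cb <- rc$CB[idx] + ifelse(in_helix, helix_offsets[2], 0) +
      stats::rnorm(n_res, 0, noise_sd)
    h <- 8.3 + stats::rnorm(n_res, 0, 0.4)
    nn <- 119 + stats::rnorm(n_res, 0, 3)
    ref <- shift_table(data.frame(resnum = 1:n_res, restype = types,
                                  H = h, N = nn, CA = ca, CB = cb))
    mod <- ref
    hit <- ref$resnum %in% perturbed
    amide_noise <- noise_sd / 10
    mod$H <- ref$H + ifelse(hit, dd_h, 0) +
      stats::rnorm(n_res, 0, amide_noise)
    mod$N <- ref$N + ifelse(hit, dd_n, 0) +
      stats::rnorm(n_res, 0, amide_noise * 5)
    mod$CA <- ref$CA + stats::rnorm(n_res, 0, amide_noise)
    mod$CB <- ref$CB + stats::rnorm(n_res, 0, amide_noise)
    list(ref = ref, mod = mod,
         truth = list(seed = seed, helix_segments = helix_segments,
                      perturbed = perturbed,
                      dd_expected = sqrt(dd_h^2 + (dd_n / 5)^2)))
  })
}
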