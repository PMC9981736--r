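# Protein-protein interface analysis: residue contacts, Shrake-Rupley
# solvent-accessible surface area, buried interface area, crystal-lattice
# contact scanning and salt-bridge detection.

#' Residue-residue contacts between two atom groups
#'
#' One record per residue pair whose minimum cross-group heavy-atom distance
#' is at most `loose`; pairs within `tight` are flagged. The two-threshold
#' convention (6 / 8 Angstrom by default) matches the usual reading of
#' covariation hits against a structural model.
#'
#' @param groupA,groupB atom data frames (e.g. from [select_atoms()]).
#' @param loose,tight distance thresholds in Angstrom, `loose >= tight`.
#' @return a `ContactSet`: data.frame (`chain_a`, `resseq_a`, `resname_a`,
#'   `chain_b`, `resseq_b`, `resname_b`, `distance`, `tight`) with the
#'   thresholds as attributes.
#' @export
residue_contacts <- function(groupA, groupB, loose = 8.0, tight = 6.0) {
  if (!nrow(groupA) || !nrow(groupB))
    stop("residue_contacts: empty atom group")
  if (loose < tight) stop("residue_contacts: need loose >= tight")
  d2 <- cross_dist2(groupA[, c("x", "y", "z")], groupB[, c("x", "y", "z")])
  ra <- paste(groupA$chain, groupA$resseq, groupA$resname)
  rb <- paste(groupB$chain, groupB$resseq, groupB$resname)
  # min distance per residue pair
  dmin <- tapply(sqrt(as.vector(d2)),
                 list(rep(ra, times = nrow(groupB)),
                      rep(rb, each = nrow(groupA))), min)
  hit <- which(dmin <= loose, arr.ind = TRUE)
  spl <- function(v) do.call(rbind, strsplit(v, " "))
  if (nrow(hit)) {
    pa <- spl(rownames(dmin)[hit[, 1]]); pb <- spl(colnames(dmin)[hit[, 2]])
    out <- data.frame(
      chain_a = pa[, 1], resseq_a = as.integer(pa[, 2]), resname_a = pa[, 3],
      chain_b = pb[, 1], resseq_b = as.integer(pb[, 2]), resname_b = pb[, 3],
      distance = dmin[hit], stringsAsFactors = FALSE)
    out$tight <- out$distance <= tight
    out <- out[order(out$chain_a, out$resseq_a, out$chain_b, out$resseq_b), ,
               drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(chain_a = character(), resseq_a = integer(),
                      resname_a = character(), chain_b = character(),
                      resseq_b = integer(), resname_b = character(),
                      distance = numeric(), tight = logical())
  }
  attr(out, "loose") <- loose; attr(out, "tight") <- tight
  class(out) <- c("ContactSet", class(out))
  out
}

# quasi-uniform unit sphere points (golden-spiral), deterministic
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by quasi-uniform sphere-point sampling: each atom's sphere
#' of radius `r_vdw + probe` is sampled with `n_points` points and the
#' fraction not buried inside any neighbour's probe-expanded sphere is
#' converted to area.
#'
#' @param atoms atom data frame (heavy atoms; e.g. from [select_atoms()]) or
#'   a `Structure` (its default heavy-atom selection is used).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sampling points per atom (default 960; minimum 92).
#' @param default_radius fallback van der Waals radius for unknown elements
#'   (with a warning).
#' @return numeric vector of per-atom areas (Angstrom^2); total SASA is its
#'   sum.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960,
                               default_radius = 1.70) {
  if (inherits(atoms, "Structure")) atoms <- select_atoms(atoms)
  if (n_points < 92) stop("shrake_rupley_sasa: n_points must be >= 92")
  n <- nrow(atoms)
  if (!n) return(numeric())
  el <- toupper(atoms$element)
  r <- unname(VDW_RADII[el])
  if (anyNA(r)) {
    warning("shrake_rupley_sasa: unknown element(s) ",
            paste(unique(el[is.na(r)]), collapse = ", "),
            " - using default radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rs <- r + probe
  pts <- sphere_points(n_points)
  # neighbour lists via a single squared-distance pass (fixtures are small)
  d2 <- cross_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    cand <- which(d2[i, ] < (rs[i] + rs)^2 & seq_len(n) != i)
    p <- sweep(pts * rs[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in cand) {
      if (!any(acc)) break
      dj <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj >= rs[j]^2
    }
    area[i] <- 4 * pi * rs[i]^2 * sum(acc) / n_points
  }
  area
}

#' Buried interface area between two atom groups
#'
#' Computes `area = (SASA(A alone) + SASA(B alone) - SASA(A union B)) / 2`,
#' the two-side average of the solvent-accessible area lost on complexation;
#' the per-side buried areas are reported too so either convention can be
#' read off.
#'
#' @param s a `Structure` (or `CompositeModel`).
#' @param groupA,groupB disjoint chain-id vectors, or atom data frames.
#' @param probe probe radius (Angstrom).
#' @param n_points sphere points per atom.
#' @return an `InterfaceReport`: list with `area`, `area_A`, `area_B`
#'   (per-side burial), `per_residue_burial` (data frame), and the SASA
#'   totals of the three calculations.
#' @export
interface_area <- function(s, groupA, groupB, probe = 1.4, n_points = 960) {
  if (inherits(s, "CompositeModel")) s <- s$assembly
  if (is.data.frame(groupA)) { A <- groupA; B <- groupB }
  else {
    if (length(intersect(groupA, groupB)))
      stop("interface_area: chain groups overlap")
    all_at <- select_atoms(s)
    A <- all_at[all_at$chain %in% groupA, , drop = FALSE]
    B <- all_at[all_at$chain %in% groupB, , drop = FALSE]
  }
  sA <- shrake_rupley_sasa(A, probe, n_points)
  sB <- shrake_rupley_sasa(B, probe, n_points)
  sAB <- shrake_rupley_sasa(rbind(A, B), probe, n_points)
  nA <- nrow(A)
  burial_A <- sA - sAB[seq_len(nA)]
  burial_B <- sB - sAB[nA + seq_len(nrow(B))]
  per_res <- rbind(
    data.frame(chain = A$chain, resseq = A$resseq, burial = burial_A),
    data.frame(chain = B$chain, resseq = B$resseq, burial = burial_B))
  per_res <- stats::aggregate(burial ~ chain + resseq, per_res, sum)
  structure(list(
    area = (sum(sA) + sum(sB) - sum(sAB)) / 2,
    area_A = sum(burial_A), area_B = sum(burial_B),
    sasa_A = sum(sA), sasa_B = sum(sB), sasa_AB = sum(sAB),
    per_residue_burial = per_res[per_res$burial > 1e-9, , drop = FALSE]),
    class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf("InterfaceReport: buried area %.1f A^2 (per side %.1f / %.1f)\n",
              x$area, x$area_A, x$area_B))
  invisible(x)
}

#' Scan crystal-lattice contacts
#'
#' Expands the crystal symmetry out to `radius` and computes the buried
#' interface area between the deposited copy and every contacting mate,
#' sorted by area (largest first). A structure whose largest lattice
#' interface stays small (e.g. below ~275 Angstrom^2) can be called
#' monomeric in the lattice.
#'
#' @param s `Structure` with cell and symmetry operators.
#' @param radius symmetry-expansion contact radius (Angstrom, default 5).
#' @param probe probe radius.
#' @param n_points sphere points per atom.
#' @return list of `list(label, report)` where `report` is an
#'   [interface_area()] result, sorted by decreasing `area`.
#' @export
crystal_contact_scan <- function(s, radius = 5.0, probe = 1.4,
                                 n_points = 960) {
  mates <- expand_symmetry(s, radius)
  self_atoms <- select_atoms(s)
  out <- lapply(mates, function(m) {
    mate_atoms <- select_atoms(m$structure)
    list(label = m$label,
         report = interface_area(s, self_atoms, mate_atoms,
                                 probe = probe, n_points = n_points))
  })
  out[order(-vapply(out, function(e) e$report$area, 0))]
}

ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))

#' Detect salt bridges
#'
#' Finds Asp/Glu side-chain oxygen to Arg/Lys side-chain nitrogen pairs
#' within `cutoff`, deduplicated per residue pair at the minimum O-N
#' distance. Histidine can optionally be counted as basic.
#'
#' @param s a `Structure` (or `CompositeModel`).
#' @param cutoff O-N distance cutoff in Angstrom (default 4.0).
#' @param scope `"intra-chain"`, `"inter-chain"` or `"both"`.
#' @param include_his count His ND1/NE2 as basic (default `FALSE`).
#' @return data.frame (`chain_acid`, `resseq_acid`, `resname_acid`,
#'   `chain_base`, `resseq_base`, `resname_base`, `distance`).
#' @export
detect_salt_bridges <- function(s, cutoff = 4.0,
                                scope = c("both", "intra-chain",
                                          "inter-chain"),
                                include_his = FALSE) {
  scope <- match.arg(scope)
  if (inherits(s, "CompositeModel")) s <- s$assembly
  a <- select_atoms(s)
  basic <- BASIC_N[if (include_his) c("ARG", "LYS", "HIS") else c("ARG", "LYS")]
  is_ac <- mapply(function(rn, at) !is.null(ACIDIC_O[[rn]]) &&
                    at %in% ACIDIC_O[[rn]], a$resname, a$atom)
  is_ba <- mapply(function(rn, at) !is.null(basic[[rn]]) &&
                    at %in% basic[[rn]], a$resname, a$atom)
  ac <- a[is_ac, , drop = FALSE]; ba <- a[is_ba, , drop = FALSE]
  empty <- data.frame(chain_acid = character(), resseq_acid = integer(),
                      resname_acid = character(), chain_base = character(),
                      resseq_base = integer(), resname_base = character(),
                      distance = numeric())
  if (!nrow(ac) || !nrow(ba)) return(empty)
  d <- sqrt(cross_dist2(ac[, c("x", "y", "z")], ba[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(
    chain_acid = ac$chain[hit[, 1]], resseq_acid = ac$resseq[hit[, 1]],
    resname_acid = ac$resname[hit[, 1]],
    chain_base = ba$chain[hit[, 2]], resseq_base = ba$resseq[hit[, 2]],
    resname_base = ba$resname[hit[, 2]],
    distance = d[hit], stringsAsFactors = FALSE)
  if (scope == "intra-chain") out <- out[out$chain_acid == out$chain_base, ]
  if (scope == "inter-chain") out <- out[out$chain_acid != out$chain_base, ]
  if (!nrow(out)) return(empty)
  key <- paste(out$chain_acid, out$resseq_acid, out$chain_base,
               out$resseq_base)
  out <- do.call(rbind, lapply(split(out, key), function(g)
    g[which.min(g$distance), , drop = FALSE]))
  out <- out[order(out$chain_acid, out$resseq_acid, out$resseq_base), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
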