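# Template-grafted modeling of a phosphotransfer-competent DHp/Rec complex:
# each donor domain is anchored onto its counterpart in a template complex by
# a Kabsch fit of user-named anchor helices, then the pieces are reassembled
# into one structure and the transfer geometry and steric quality assessed.

#' Specify a grafting anchor
#'
#' An anchor names the CA positions of the donor component that are fitted
#' onto the corresponding CA positions of the template chain (ranges-mode
#' matching: both selections must cover equally many residues). Typical
#' anchors are interface helices, e.g. the C-terminal half of DHp alpha1' and
#' the N-terminal half of alpha2', or the Rec alpha1 helix.
#'
#' @param component_selection `Selection` on the donor (restricted to CA).
#' @param template_selection `Selection` on the template (restricted to CA).
#' @param label free-text label.
#' @return an `AnchorSpec`.
#' @export
anchor_spec <- function(component_selection, template_selection, label = "") {
  stopifnot(inherits(component_selection, "Selection"),
            inherits(template_selection, "Selection"))
  structure(list(component_selection = component_selection,
                 template_selection = template_selection, label = label),
            class = "AnchorSpec")
}

#' Graft donor domains onto a template complex
#'
#' For each `(donor, anchor)` pair, the donor's anchor CA atoms are fitted
#' onto the template's anchor CA atoms with [kabsch_fit()] and the whole
#' donor is rigidly transformed accordingly - no side-chain adjustment of any
#' kind. The transformed donors are reassembled into a single structure with
#' fresh chain ids `A`, `B`, ... in input order; original chain ids and the
#' per-component transform and anchor rmsd are kept as provenance.
#'
#' @param template `Structure` of the template complex.
#' @param components list of `list(structure = donor, anchor = AnchorSpec)`.
#' @param anchor_rmsd_warn warn when an anchor fit rmsd exceeds this ceiling
#'   (Angstrom, default 2.0); the graft still proceeds.
#' @return a `CompositeModel`: list with `assembly` (Structure) and
#'   `provenance` (per-component source id, anchor, transform, anchor rmsd,
#'   original chain ids, assigned chain id).
#' @export
graft_complex <- function(template, components, anchor_rmsd_warn = 2.0) {
  stopifnot(inherits(template, "Structure"), length(components) >= 1)
  next_chain <- 1L
  assembly_atoms <- NULL
  provenance <- list()
  for (i in seq_along(components)) {
    comp <- components[[i]]
    donor <- comp$structure
    anc <- comp$anchor
    stopifnot(inherits(donor, "Structure"), inherits(anc, "AnchorSpec"))
    ca_d <- ca_trace(donor, anc$component_selection)
    ca_t <- ca_trace(template, anc$template_selection)
    if (nrow(ca_d) != nrow(ca_t))
      stop("graft_complex: anchor '", anc$label, "' resolves to ",
           nrow(ca_d), " donor vs ", nrow(ca_t), " template CA atoms")
    if (nrow(ca_d) < 3)
      stop("graft_complex: anchor '", anc$label, "' has <3 CA pairs")
    fit <- kabsch_fit(as.matrix(ca_d[, c("x", "y", "z")]),
                      as.matrix(ca_t[, c("x", "y", "z")]))
    if (fit$rmsd > anchor_rmsd_warn)
      warning(sprintf("graft_complex: anchor '%s' rmsd %.2f A above ceiling %.2f A",
                      anc$label, fit$rmsd, anchor_rmsd_warn))
    placed <- apply_transform(donor, fit$transform)
    a <- placed$atoms
    a$orig_chain <- a$chain
    # each original chain of the donor gets its own fresh id
    orig <- unique(a$chain)
    fresh <- LETTERS[next_chain + seq_along(orig) - 1L]
    next_chain <- next_chain + length(orig)
    a$chain <- fresh[match(a$chain, orig)]
    assembly_atoms <- rbind(assembly_atoms, a)
    provenance[[i]] <- list(source = donor$id, chain = fresh,
                            original_chains = orig,
                            anchor = anc, transform = fit$transform,
                            anchor_rmsd = fit$rmsd)
  }
  assembly <- new_structure(
    assembly_atoms[, setdiff(names(assembly_atoms),
                             c("orig_chain", "is_water", "is_hydrogen"))],
    id = paste0("graft(", template$id, ")"))
  structure(list(assembly = assembly, provenance = provenance,
                 template_id = template$id),
            class = "CompositeModel")
}

#' @export
print.CompositeModel <- function(x, ...) {
  cat(sprintf("CompositeModel from template '%s': %d components\n",
              x$template_id, length(x$provenance)))
  for (p in x$provenance)
    cat(sprintf("  chain %s <- %s (anchor '%s', rmsd %.3f A)\n",
                paste(p$chain, collapse = ","), p$source,
                p$anchor$label, p$anchor_rmsd))
  invisible(x)
}

#' Distance between the phosphotransfer histidine and aspartate
#'
#' Measures the Euclidean distance between one named atom of the active
#' histidine and one of the active aspartate in a composite model (or plain
#' structure). The default convention is His NE2 to Asp CG; the minimum over
#' the Asp carboxylate oxygens (OD1/OD2) is reported alongside since the
#' printed literature distances do not name atoms.
#'
#' @param m `CompositeModel` or `Structure`.
#' @param his,asp residue specs `list(chain =, resseq =)`.
#' @param atom_pair length-2 character: His atom, Asp atom.
#' @return list with `distance` (Angstrom, for `atom_pair`), `distance_min_O`
#'   (His atom to nearest OD1/OD2), and the convention used.
#' @export
measure_transfer_geometry <- function(m, his, asp,
                                      atom_pair = c("NE2", "CG")) {
  s <- if (inherits(m, "CompositeModel")) m$assembly else m
  stopifnot(inherits(s, "Structure"))
  grab <- function(spec, atom) {
    a <- s$atoms
    hit <- a[a$chain == spec$chain & a$resseq == spec$resseq &
               a$atom == atom, , drop = FALSE]
    if (!nrow(hit))
      stop("measure_transfer_geometry: atom ", atom, " of residue ",
           spec$chain, ":", spec$resseq, " not found")
    as.numeric(hit[1, c("x", "y", "z")])
  }
  h <- grab(his, atom_pair[1])
  d <- grab(asp, atom_pair[2])
  dist <- sqrt(sum((h - d)^2))
  od <- lapply(c("OD1", "OD2"), function(at)
    tryCatch(grab(asp, at), error = function(e) NULL))
  od <- Filter(Negate(is.null), od)
  dmin <- if (length(od))
    min(vapply(od, function(o) sqrt(sum((h - o)^2)), 0)) else NA_real_
  list(distance = dist, distance_min_O = dmin,
       convention = paste(atom_pair, collapse = "-"))
}

#' Count steric clashes between two chain groups
#'
#' Lists every cross-group atom pair of the requested class closer than
#' `cutoff`, in deterministic (chainA, resseqA, atomA, chainB, resseqB,
#' atomB) order; near-misses between `cutoff` and `near_cutoff` are reported
#' separately.
#'
#' @param m `CompositeModel` or `Structure`.
#' @param groupA,groupB disjoint character vectors of chain ids.
#' @param atom_class selection class, default `"mainchain+CB"`.
#' @param cutoff clash distance in Angstrom (default 3.0).
#' @param near_cutoff upper bound of the near-miss band (default 3.5).
#' @return a `ClashReport`: list with `clashes` and `near_misses` data frames
#'   (`chain_a`, `resseq_a`, `atom_a`, `chain_b`, `resseq_b`, `atom_b`,
#'   `distance`), `n_clashes`, `atom_class`, `cutoff`.
#' @export
count_interdomain_clashes <- function(m, groupA, groupB,
                                      atom_class = "mainchain+CB",
                                      cutoff = 3.0, near_cutoff = 3.5) {
  s <- if (inherits(m, "CompositeModel")) m$assembly else m
  if (length(intersect(groupA, groupB)))
    stop("count_interdomain_clashes: chain groups overlap")
  if (!length(groupA) || !length(groupB))
    stop("count_interdomain_clashes: empty chain group")
  sel <- atom_selection(atom_class = atom_class)
  a <- select_atoms(s, sel); a <- a[a$chain %in% groupA, , drop = FALSE]
  b <- select_atoms(s, sel); b <- b[b$chain %in% groupB, , drop = FALSE]
  d2 <- cross_dist2(a[, c("x", "y", "z")], b[, c("x", "y", "z")])
  hit <- which(d2 < near_cutoff^2, arr.ind = TRUE)
  tab <- data.frame(
    chain_a = a$chain[hit[, 1]], resseq_a = a$resseq[hit[, 1]],
    atom_a = a$atom[hit[, 1]],
    chain_b = b$chain[hit[, 2]], resseq_b = b$resseq[hit[, 2]],
    atom_b = b$atom[hit[, 2]],
    distance = sqrt(d2[hit]), stringsAsFactors = FALSE)
  tab <- tab[order(tab$chain_a, tab$resseq_a, tab$atom_a,
                   tab$chain_b, tab$resseq_b, tab$atom_b), , drop = FALSE]
  clashes <- tab[tab$distance < cutoff, , drop = FALSE]
  near <- tab[tab$distance >= cutoff, , drop = FALSE]
  structure(list(clashes = clashes, near_misses = near,
                 n_clashes = nrow(clashes), atom_class = atom_class,
                 cutoff = cutoff),
            class = "ClashReport")
}

#' @export
print.ClashReport <- function(x, ...) {
  cat(sprintf("ClashReport (%s, cutoff %.1f A): %d clash%s, %d near-miss%s\n",
              x$atom_class, x$cutoff, x$n_clashes,
              if (x$n_clashes == 1) "" else "es", nrow(x$near_misses),
              if (nrow(x$near_misses) == 1) "" else "es"))
  invisible(x)
}
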