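# Rigid-body least-squares superposition (Kabsch), residue matching across
# homologs, and iterative outlier-pruned fitting.

#' Construct a rigid transform
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric.
#' @return object of class `RigidTransform`; applying it maps `x` to
#'   `R x + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rigid_transform: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rigid_transform: rotation determinant is not +1 (improper)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Invert a rigid transform
#' @param t a `RigidTransform`.
#' @return the inverse `RigidTransform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `RigidTransform`s.
#' @return `RigidTransform` equal to `x -> a(b(x))`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

transform_points <- function(xyz, t) {
  sweep(as.matrix(xyz) %*% t(t$rotation), 2, t$translation, "+")
}

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between the
#' transformed `moving` points and the `fixed` points.
#'
#' @param moving,fixed n x 3 coordinate matrices with matched rows, n >= 3.
#' @return a `SuperpositionResult`: list with `transform` (RigidTransform),
#'   `rmsd` (Angstrom), `n_retained`, `retained` (row indices),
#'   `n_iterations = 1`.
#' @export
kabsch_fit <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3)
    stop("kabsch_fit: point sets must be equal-sized n x 3 matrices")
  n <- nrow(moving)
  if (n < 3) stop("kabsch_fit: need at least 3 point pairs")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  sv <- svd(crossprod(P, Q))   # H = P^T Q
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("kabsch_fit: degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cf - as.numeric(R %*% cm)
  tf <- rigid_transform(R, tr)
  resid <- transform_points(moving, tf) - fixed
  rmsd <- sqrt(mean(rowSums(resid^2)))
  structure(list(transform = tf, rmsd = rmsd, n_retained = n,
                 retained = seq_len(n), n_iterations = 1L),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd %.3f A over %d pairs (%d iteration%s)\n",
              x$rmsd, x$n_retained, x$n_iterations,
              if (x$n_iterations == 1) "" else "s"))
  invisible(x)
}

#' Match residues between two structures
#'
#' Builds the residue correspondence used for superposition. In `"sequence"`
#' mode the one-letter CA-trace sequences are aligned globally with end-gap
#' free scoring (BLOSUM62, gap open 10 / extend 0.5); aligned non-gap columns
#' become pairs. In `"ranges"` mode the residue ranges of the two selections
#' are zipped positionally and must cover equally many residues.
#'
#' @param a,b `Structure`s.
#' @param sel_a,sel_b `Selection`s restricting each side.
#' @param mode `"sequence"` or `"ranges"`.
#' @return a `ResiduePairing`: data.frame with columns `chain_a`, `resseq_a`,
#'   `icode_a`, `chain_b`, `resseq_b`, `icode_b`, plus attribute `source`.
#' @export
match_residues <- function(a, b, sel_a = atom_selection(),
                           sel_b = atom_selection(),
                           mode = c("sequence", "ranges")) {
  mode <- match.arg(mode)
  ca_a <- ca_trace(a, sel_a); ca_b <- ca_trace(b, sel_b)
  if (!nrow(ca_a) || !nrow(ca_b))
    stop("match_residues: empty selection")
  if (mode == "ranges") {
    if (nrow(ca_a) != nrow(ca_b))
      stop("match_residues: ranges mode needs equal residue counts (",
           nrow(ca_a), " vs ", nrow(ca_b), ")")
    idx <- cbind(seq_len(nrow(ca_a)), seq_len(nrow(ca_b)))
  } else {
    idx <- align_sequences(paste(ca_a$aa1, collapse = ""),
                           paste(ca_b$aa1, collapse = ""))
  }
  out <- data.frame(
    chain_a = ca_a$chain[idx[, 1]], resseq_a = ca_a$resseq[idx[, 1]],
    icode_a = ca_a$icode[idx[, 1]],
    chain_b = ca_b$chain[idx[, 2]], resseq_b = ca_b$resseq[idx[, 2]],
    icode_b = ca_b$icode[idx[, 2]], stringsAsFactors = FALSE)
  attr(out, "source") <- if (mode == "sequence") "sequence-alignment"
    else "user-supplied ranges"
  class(out) <- c("ResiduePairing", class(out))
  out
}

# global end-gap-free alignment of two one-letter sequences; returns a
# 2-column matrix of matched (ungapped) position indices
align_sequences <- function(sa, sb, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("X", "A", sa)),
    Biostrings::AAString(gsub("X", "A", sb)),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gap_open, gapExtension = gap_extend, type = "overlap")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- Biostrings::start(Biostrings::pattern(al)) - 1L
  ib <- Biostrings::start(Biostrings::subject(al)) - 1L
  pairs <- matrix(0L, 0, 2)
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) pairs <- rbind(pairs, c(ia, ib))
  }
  pairs
}

paired_ca_coords <- function(a, b, pairing) {
  ca_a <- ca_trace(a, atom_selection(atom_class = "CA"))
  ca_b <- ca_trace(b, atom_selection(atom_class = "CA"))
  key_a <- paste(ca_a$chain, ca_a$resseq, ca_a$icode)
  key_b <- paste(ca_b$chain, ca_b$resseq, ca_b$icode)
  ia <- match(paste(pairing$chain_a, pairing$resseq_a, pairing$icode_a), key_a)
  ib <- match(paste(pairing$chain_b, pairing$resseq_b, pairing$icode_b), key_b)
  ok <- !is.na(ia) & !is.na(ib)
  list(moving = as.matrix(ca_a[ia[ok], c("x", "y", "z")]),
       fixed = as.matrix(ca_b[ib[ok], c("x", "y", "z")]),
       keep = which(ok))
}

#' Iterative outlier-pruned superposition
#'
#' Repeatedly fits the retained residue pairs with [kabsch_fit()] and drops
#' pairs whose post-fit CA-CA distance exceeds
#' `max(cutoff_factor * rmsd, abs_cutoff)`, until the retained set is stable
#' or `max_iter` is reached. This mirrors the usual structure-comparison
#' practice of reporting an RMSD over a pruned subset of matched positions.
#'
#' @param a moving `Structure`; `b` fixed `Structure`.
#' @param pairing a `ResiduePairing` from [match_residues()].
#' @param cutoff_factor multiple of the current rmsd beyond which a pair is
#'   pruned (default 2.0).
#' @param abs_cutoff absolute pruning floor in Angstrom (default 3.5).
#' @param max_iter maximum number of fit/prune rounds (default 10).
#' @return a `SuperpositionResult` whose `retained` indexes rows of
#'   `pairing`; `retained_pairs` carries the pruned `ResiduePairing`.
#' @export
iterative_superpose <- function(a, b, pairing, cutoff_factor = 2.0,
                                abs_cutoff = 3.5, max_iter = 10L) {
  pc <- paired_ca_coords(a, b, pairing)
  mov <- pc$moving; fix <- pc$fixed
  if (nrow(mov) < 3) stop("iterative_superpose: fewer than 3 usable pairs")
  retained <- seq_len(nrow(mov))
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- kabsch_fit(mov[retained, , drop = FALSE],
                      fix[retained, , drop = FALSE])
    d <- sqrt(rowSums((transform_points(mov, fit$transform) - fix)^2))
    cut <- max(cutoff_factor * fit$rmsd, abs_cutoff)
    keep <- retained[d[retained] <= cut]
    if (length(keep) < 3)
      stop("iterative_superpose: pruning left <3 pairs at iteration ", it)
    if (length(keep) == length(retained)) { retained <- keep; break }
    retained <- keep
  }
  fit <- kabsch_fit(mov[retained, , drop = FALSE],
                    fix[retained, , drop = FALSE])
  res <- fit
  res$n_iterations <- it
  res$n_retained <- length(retained)
  res$retained <- pc$keep[retained]
  res$retained_pairs <- pairing[pc$keep[retained], , drop = FALSE]
  res
}

#' Apply a rigid transform to a Structure
#'
#' Maps every atom coordinate `x` to `R x + t`; all other fields are left
#' untouched.
#' @param s a `Structure`.
#' @param t a `RigidTransform`.
#' @return the transformed `Structure`.
#' @export
apply_transform <- function(s, t) {
  stopifnot(inherits(s, "Structure"), inherits(t, "RigidTransform"))
  xyz <- transform_points(as.matrix(s$atoms[, c("x", "y", "z")]), t)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
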