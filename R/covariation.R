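# Pairwise column-coupling analysis of an alignment: mutual information with
# average-product correction (APC), z-standardization, per-pair substitution
# tables, charge-reversal statistics, and the coupling-vs-distance agreement
# analysis against a structural model.

#' Mutual-information covariation scores with APC correction
#'
#' For every retained column pair (i, j) the mutual information of the
#' weighted, pseudocounted joint amino-acid distribution is computed on
#' pairwise-complete rows (rows gapped at i or j are dropped for that pair),
#' corrected with the average-product correction
#' `APC(i, j) = MIbar(i) * MIbar(j) / MIbar`, and the corrected scores are
#' z-standardized over all retained pairs. This is a transparent stand-in
#' for heavier pseudolikelihood coupling inference: peaks above `z = 3`
#' flag strongly covarying residue pairs.
#'
#' @param a an `Alignment`.
#' @param weights per-row weights (default [sequence_weights()] at 0.8).
#' @param pseudocount total pseudocount mass per joint table (default 0.5,
#'   spread uniformly over the 400 cells).
#' @param max_gap_fraction columns with a larger (weighted) gap fraction are
#'   excluded (default 0.5).
#' @param min_n_eff refuse to score below this effective sequence number
#'   (default 20).
#' @return a `CovariationResult`: list with symmetric matrices `mi`, `apc`
#'   (MI minus correction) and `z`, the retained column indices, and the
#'   column -> residue number map `numbers`.
#' @export
covariation_scores <- function(a, weights = NULL, pseudocount = 0.5,
                               max_gap_fraction = 0.5, min_n_eff = 20) {
  stopifnot(inherits(a, "Alignment"))
  w <- weights %||% sequence_weights(a)
  n_eff <- sum(w)
  if (n_eff < min_n_eff)
    stop("covariation_scores: effective sequence number ", round(n_eff, 1),
         " below floor ", min_n_eff,
         " - add sequences or lower the identity threshold")
  m <- a$mat
  L <- ncol(m)
  gapf <- colSums((m == "-") * w) / n_eff
  keep <- which(gapf <= max_gap_fraction)
  if (length(keep) < 2)
    stop("covariation_scores: fewer than 2 non-gap-dominated columns")
  # one-hot encoding (gap rows all-zero) -> all joint counts in one crossprod
  K <- length(keep)
  X <- matrix(0, nrow(m), K * 20)
  for (jj in seq_len(K)) {
    idx <- match(m[, keep[jj]], AA20)
    ok <- !is.na(idx)
    X[cbind(which(ok), (jj - 1) * 20 + idx[ok])] <- 1
  }
  Xw <- X * w
  J <- crossprod(Xw, X)   # (K*20) x (K*20): weighted joint counts
  mi <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    bi <- (i - 1) * 20 + 1:20
    for (j in (i + 1):K) {
      bj <- (j - 1) * 20 + 1:20
      cij <- J[bi, bj]
      tot <- sum(cij)
      if (tot <= 0) next
      f <- (cij + pseudocount / 400) / (tot + pseudocount)
      fi <- rowSums(f); fj <- colSums(f)
      e <- outer(fi, fj)
      pos <- f > 0
      mi[i, j] <- mi[j, i] <- sum(f[pos] * log2(f[pos] / e[pos]))
    }
  }
  mibar_i <- rowSums(mi) / (K - 1)
  mibar <- sum(mi[upper.tri(mi)]) * 2 / (K * (K - 1))
  apc <- mi - outer(mibar_i, mibar_i) / mibar
  diag(apc) <- 0
  ut <- apc[upper.tri(apc)]
  z <- (apc - mean(ut)) / stats::sd(ut)
  diag(z) <- 0
  nums <- column_numbers(a)
  structure(list(mi = mi, apc = apc, z = z, columns = keep,
                 numbers = nums[keep], n_eff = n_eff,
                 threshold = 3.0),
            class = "CovariationResult")
}

#' Scored pairs above a z threshold
#' @param cv a `CovariationResult`.
#' @param threshold z-score cutoff (default: the stored 3.0).
#' @return data.frame `col_i`, `col_j`, `number_i`, `number_j`, `mi`, `z`,
#'   ordered by decreasing z.
#' @export
top_couplings <- function(cv, threshold = cv$threshold) {
  ut <- which(upper.tri(cv$z) & cv$z > threshold, arr.ind = TRUE)
  out <- data.frame(col_i = cv$columns[ut[, 1]], col_j = cv$columns[ut[, 2]],
                    number_i = cv$numbers[ut[, 1]],
                    number_j = cv$numbers[ut[, 2]],
                    mi = cv$mi[ut], z = cv$z[ut])
  out[order(-out$z), , drop = FALSE]
}

#' Joint substitution table for a column pair
#'
#' Weighted 20x20 joint residue counts for alignment columns (i, j), rows
#' gapped at either column excluded; rows/columns follow the fixed
#' alphabetical amino-acid order.
#'
#' @param a an `Alignment`.
#' @param i,j column indices (alignment numbering).
#' @param weights per-row weights (default: all 1).
#' @return a `PairSubstitutionTable`: list with `joint` (20x20),
#'   `marginal_i`, `marginal_j`, `n_effective`.
#' @export
pair_substitution_table <- function(a, i, j, weights = NULL) {
  m <- a$mat
  stopifnot(i >= 1, j >= 1, i <= ncol(m), j <= ncol(m))
  w <- weights %||% rep(1, nrow(m))
  ri <- m[, i]; rj <- m[, j]
  ok <- ri != "-" & rj != "-"
  joint <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  if (any(ok)) {
    idx <- cbind(match(ri[ok], AA20), match(rj[ok], AA20))
    for (k in seq_len(sum(ok)))
      joint[idx[k, 1], idx[k, 2]] <- joint[idx[k, 1], idx[k, 2]] + w[ok][k]
  }
  structure(list(joint = joint, marginal_i = rowSums(joint),
                 marginal_j = colSums(joint), n_effective = sum(joint),
                 columns = c(i, j)),
            class = "PairSubstitutionTable")
}

#' Charge-reversal statistics of a pair substitution table
#'
#' Classifies the residues of a joint table into basic (+: K, R, optionally
#' H), acidic (-: D, E) and other, and reports the fraction of (+,-), (-,+)
#' and remaining pairs plus the reversal balance
#' `min(f+-, f-+) / max(f+-, f-+)`. A balance near 1 means the ion pair is
#' observed about equally often in both orientations - the signature of a
#' covarying salt bridge that tolerates charge reversal.
#'
#' @param t a `PairSubstitutionTable`.
#' @param his_positive count histidine as basic (default `FALSE`).
#' @return list `f_plus_minus`, `f_minus_plus`, `f_other`, `balance`.
#' @export
charge_reversal_fraction <- function(t, his_positive = FALSE) {
  if (t$n_effective <= 0) {
    warning("charge_reversal_fraction: empty substitution table")
    return(list(f_plus_minus = NA_real_, f_minus_plus = NA_real_,
                f_other = NA_real_, balance = NA_real_))
  }
  pos <- c("K", "R", if (his_positive) "H")
  neg <- c("D", "E")
  f_pm <- sum(t$joint[pos, neg]) / t$n_effective
  f_mp <- sum(t$joint[neg, pos]) / t$n_effective
  balance <- if (max(f_pm, f_mp) == 0) NA_real_
    else min(f_pm, f_mp) / max(f_pm, f_mp)
  list(f_plus_minus = f_pm, f_minus_plus = f_mp,
       f_other = 1 - f_pm - f_mp, balance = balance)
}

#' Import an externally computed coupling table
#'
#' Reads a plain-text table of residue pairs and scores (columns: residue i,
#' residue j, score, whitespace- or comma-separated, optional header), so
#' agreement analyses can be run verbatim on scores from an external
#' coupling engine.
#'
#' @param path file path.
#' @return data.frame `number_i`, `number_j`, `z`.
#' @export
read_coupling_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!is.numeric(tab[[1]])) tab <- tab[-1, , drop = FALSE]  # header row
  stopifnot(ncol(tab) >= 3)
  data.frame(number_i = as.integer(tab[[1]]),
             number_j = as.integer(tab[[2]]),
             z = as.numeric(tab[[3]]))
}

#' Agreement between covariation peaks and model distances
#'
#' Joins every scored pair above the threshold to the minimum heavy-atom
#' residue-residue distance in a structural model (a `ContactSet` from
#' [residue_contacts()], keyed by residue numbers) and classifies each as
#' `red` (< tight), `black` (< loose) or `miss`; precision is the fraction
#' of mapped peaks within each distance class. Pairs without a model
#' distance are reported separately, as are peaks whose residue pair could
#' form an ion pair (Asp/Glu against Arg/Lys consensus).
#'
#' @param cv `CovariationResult` or an imported coupling data.frame
#'   (`number_i`, `number_j`, `z`).
#' @param contacts `ContactSet` with residue numbers matching the coupling
#'   numbering (`resseq_a` on the i side, `resseq_b` on the j side).
#' @param score_threshold z cutoff (default 3.0).
#' @param tight,loose distance classes in Angstrom (defaults 6 / 8).
#' @param region optional list `list(i = c(lo, hi), j = c(lo, hi))`
#'   restricting the residue numbers considered on each axis.
#' @return an `AgreementReport`: list with `pairs` (data.frame: numbers, z,
#'   distance, class), `precision_tight`, `precision_loose`, `n_unmapped`.
#' @export
covariation_vs_distance <- function(cv, contacts, score_threshold = 3.0,
                                    tight = 6.0, loose = 8.0,
                                    region = NULL) {
  peaks <- if (inherits(cv, "CovariationResult"))
    top_couplings(cv, score_threshold)
  else cv[cv$z > score_threshold, , drop = FALSE]
  if (!is.null(region)) {
    keep <- peaks$number_i >= region$i[1] & peaks$number_i <= region$i[2] &
      peaks$number_j >= region$j[1] & peaks$number_j <= region$j[2]
    peaks <- peaks[keep, , drop = FALSE]
  }
  dist_key <- c(
    stats::setNames(contacts$distance,
                    paste(contacts$resseq_a, contacts$resseq_b)),
    stats::setNames(contacts$distance,
                    paste(contacts$resseq_b, contacts$resseq_a)))
  d <- unname(dist_key[paste(peaks$number_i, peaks$number_j)])
  cls <- rep("miss", length(d))
  cls[!is.na(d) & d < loose] <- "black"
  cls[!is.na(d) & d < tight] <- "red"
  # treat absent contact entries as "miss" (distance beyond the loose net)
  pairs <- data.frame(number_i = peaks$number_i, number_j = peaks$number_j,
                      z = peaks$z, distance = d, class = cls,
                      stringsAsFactors = FALSE)
  n <- nrow(pairs)
  structure(list(
    pairs = pairs,
    precision_tight = if (n) mean(pairs$class == "red") else NA_real_,
    precision_loose = if (n) mean(pairs$class %in% c("red", "black"))
      else NA_real_,
    n_unmapped = sum(is.na(d)), tight = tight, loose = loose,
    score_threshold = score_threshold),
    class = "AgreementReport")
}

#' @export
print.AgreementReport <- function(x, ...) {
  n <- nrow(x$pairs)
  cat(sprintf(
    "AgreementReport: %d peaks (z > %.1f); precision %.2f (<%.0f A) / %.2f (<%.0f A)\n",
    n, x$score_threshold, x$precision_tight %||% NA, x$tight,
    x$precision_loose %||% NA, x$loose))
  invisible(x)
}
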