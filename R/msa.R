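# Multiple-sequence-alignment ingestion, per-column conservation profiles
# (sequence-logo information content), class-discriminative conservation
# between two Rec families, and FxSGY-type motif scanning.

#' Construct an Alignment object
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (20 amino acids plus `-`/`.` gaps; case-insensitive).
#' @param reference_row id of the row whose ungapped numbering maps columns
#'   to residue numbers (default: first row).
#' @param reference_offset integer added to the reference row's ungapped
#'   position to produce residue numbers (so `offset = 622` anchors position
#'   1 to residue 623).
#' @return object of class `Alignment`: list with `ids`, `mat` (n x L
#'   character matrix), `reference_row`, `reference_offset`.
#' @export
new_alignment <- function(seqs, reference_row = NULL, reference_offset = 0L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  w <- nchar(seqs)
  if (length(unique(w)) != 1)
    stop("new_alignment: ragged alignment - row '",
         names(seqs)[which(w != w[1])[1]], "' has width ",
         w[w != w[1]][1], " not ", w[1])
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  mat[mat == "."] <- "-"
  rownames(mat) <- names(seqs)
  ok <- matrix(mat %in% c(AA20, "-"), nrow(mat))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad))
    stop("new_alignment: illegal character '", mat[bad[1, , drop = FALSE]],
         "' in row '", rownames(mat)[bad[1, 1]], "' column ", bad[1, 2])
  reference_row <- reference_row %||% names(seqs)[1]
  if (!reference_row %in% names(seqs))
    stop("new_alignment: reference row '", reference_row, "' absent")
  structure(list(ids = names(seqs), mat = mat,
                 reference_row = reference_row,
                 reference_offset = as.integer(reference_offset)),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns (reference '%s'+%d)\n",
              nrow(x$mat), ncol(x$mat), x$reference_row,
              x$reference_offset))
  invisible(x)
}

#' Residue numbers for alignment columns
#'
#' Maps each column to the author residue number of the reference row
#' (ungapped index + offset); gap columns of the reference map to `NA`.
#' @param a an `Alignment`.
#' @return integer vector of length `ncol`.
#' @export
column_numbers <- function(a) {
  ref <- a$mat[a$reference_row, ]
  num <- cumsum(ref != "-")
  num[ref == "-"] <- NA
  as.integer(num + a$reference_offset)
}

#' Read a multiple sequence alignment
#'
#' @param path file path.
#' @param format `"fasta"` or `"stockholm"` (`"auto"` by extension/content).
#' @param ... passed to [new_alignment()] (`reference_row`,
#'   `reference_offset`).
#' @return an `Alignment`; for Stockholm input, `#=GC` annotation lines are
#'   kept in `attr(, "gc")`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm"),
                           ...) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^# STOCKHOLM", lines))) "stockholm" else "fasta"
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*$", "", names(aa))
    return(new_alignment(seqs, ...))
  }
  # Stockholm: accumulate possibly-wrapped sequence blocks
  seqs <- character(); gc <- character()
  for (l in lines) {
    if (grepl("^#=GC\\s", l)) {
      p <- strsplit(trimws(l), "\\s+")[[1]]
      gc[p[2]] <- paste0(if (is.na(gc[p[2]])) "" else gc[p[2]], p[3])
    } else if (!grepl("^(#|//)", l) && nzchar(trimws(l))) {
      p <- strsplit(trimws(l), "\\s+")[[1]]
      if (length(p) != 2) stop("read_alignment: malformed Stockholm line: ", l)
      seqs[p[1]] <- paste0(if (is.na(seqs[p[1]])) "" else seqs[p[1]], p[2])
    }
  }
  if (!length(seqs)) stop("read_alignment: no sequences in ", path)
  out <- new_alignment(seqs, ...)
  attr(out, "gc") <- as.list(gc)
  out
}

#' Write an Alignment to FASTA
#' @param a an `Alignment`.
#' @param path output path.
#' @export
write_alignment <- function(a, path) {
  writeLines(as.vector(rbind(paste0(">", a$ids),
                             apply(a$mat, 1, paste, collapse = ""))), path)
  invisible(path)
}

#' Redundancy-correcting sequence weights
#'
#' `weight(s) = 1 / #\{rows with fractional identity >= threshold to s\}`
#' (the row itself included), the standard position-independent redundancy
#' correction; the effective sequence number is `sum(weights)`. Identity is
#' the fraction of alignment columns at which the two rows carry the same
#' symbol (gaps count as a symbol).
#'
#' @param a an `Alignment`.
#' @param identity_threshold fraction in (0, 1], default 0.8.
#' @return numeric weights, one per row, with `attr(, "n_eff")`.
#' @export
sequence_weights <- function(a, identity_threshold = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  m <- a$mat
  n <- nrow(m)
  counts <- integer(n)
  for (i in seq_len(n)) {
    id <- rowMeans(m == matrix(m[i, ], n, ncol(m), byrow = TRUE))
    counts[i] <- sum(id >= identity_threshold)
  }
  w <- 1 / counts
  attr(w, "n_eff") <- sum(w)
  w
}

#' Per-column conservation profile
#'
#' Weighted, pseudocounted amino-acid frequencies per column, plus the
#' information content used for sequence logos:
#' `IC = (log2(20) - H(column)) * (1 - gap fraction)` in bits, with `H` the
#' Shannon entropy of the 20-state frequency vector (uniform-background
#' convention). Gaps are excluded from the frequencies and reported as a
#' separate gap fraction.
#'
#' @param a an `Alignment`.
#' @param weights per-row weights (default: all 1).
#' @param pseudocount total pseudocount mass spread uniformly over the 20
#'   amino acids (default 0.5).
#' @return a `ConservationProfile`: list with `freq` (L x 20 matrix), `ic`
#'   (bits), `consensus`, `gap_fraction`, `weights`, and the column -> residue
#'   number map `numbers`.
#' @export
column_profile <- function(a, weights = NULL, pseudocount = 0.5) {
  stopifnot(pseudocount >= 0)
  m <- a$mat
  w <- weights %||% rep(1, nrow(m))
  L <- ncol(m)
  freq <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  gapf <- numeric(L)
  wtot <- sum(w)
  for (j in seq_len(L)) {
    col <- m[, j]
    gapf[j] <- sum(w[col == "-"]) / wtot
    cnt <- vapply(AA20, function(aa) sum(w[col == aa]), 0)
    cnt <- cnt + pseudocount / 20
    freq[j, ] <- cnt / sum(cnt)
  }
  H <- -rowSums(ifelse(freq > 0, freq * log2(freq), 0))
  ic <- pmax(0, (log2(20) - H)) * (1 - gapf)
  structure(list(freq = freq, ic = ic,
                 consensus = AA20[max.col(freq, ties.method = "first")],
                 gap_fraction = gapf, weights = w, numbers = column_numbers(a)),
            class = "ConservationProfile")
}

#' Differential conservation between two families
#'
#' Classifies mapped column pairs of two family profiles: a column is
#' "conserved" within a family when its top amino-acid frequency reaches
#' `t_cons`. Conserved in both with the same consensus: `shared`; conserved
#' in exactly one (or in both but with different consensus residues):
#' `A-specific` / `B-specific` (different-consensus pairs yield both);
#' otherwise `unconserved`. Gap-rich columns (gap fraction above
#' `max_gap_fraction` in either family) are skipped.
#'
#' @param pA,pB `ConservationProfile`s of family A and B.
#' @param column_mapping 2-column integer matrix of (column in A, column in
#'   B) pairs; default: positional 1:1 mapping (equal-width alignments).
#' @param t_cons conservation threshold on the top frequency (default 0.7).
#' @param max_gap_fraction exclusion threshold (default 0.5).
#' @return data.frame with columns `col_a`, `col_b`, `number_a`, `number_b`,
#'   `consensus_a`, `consensus_b`, `top_freq_a`, `top_freq_b`, `class`.
#' @export
differential_conservation <- function(pA, pB, column_mapping = NULL,
                                      t_cons = 0.7,
                                      max_gap_fraction = 0.5) {
  if (is.null(column_mapping)) {
    if (length(pA$ic) != length(pB$ic))
      stop("differential_conservation: profiles differ in width; supply ",
           "column_mapping")
    column_mapping <- cbind(seq_along(pA$ic), seq_along(pB$ic))
  }
  ca <- column_mapping[, 1]; cb <- column_mapping[, 2]
  fa <- apply(pA$freq[ca, , drop = FALSE], 1, max)
  fb <- apply(pB$freq[cb, , drop = FALSE], 1, max)
  consa <- pA$consensus[ca]; consb <- pB$consensus[cb]
  keep <- pA$gap_fraction[ca] <= max_gap_fraction &
    pB$gap_fraction[cb] <= max_gap_fraction
  cls <- rep("unconserved", length(ca))
  cons_a <- fa >= t_cons; cons_b <- fb >= t_cons
  cls[cons_a & cons_b & consa == consb] <- "shared"
  cls[cons_a & (!cons_b | consa != consb)] <- "A-specific"
  cls[cons_b & (!cons_a | consa != consb)] <- "B-specific"
  cls[cons_a & cons_b & consa != consb] <- "both-specific"
  out <- data.frame(col_a = ca, col_b = cb,
                    number_a = pA$numbers[ca], number_b = pB$numbers[cb],
                    consensus_a = consa, consensus_b = consb,
                    top_freq_a = fa, top_freq_b = fb,
                    class = cls, stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Scan an alignment (or sequence) for a sequence motif
#'
#' The pattern is a string over specific residues, `x` (any), and bracketed
#' residue classes, e.g. `"FxSGY"` or `"Fx[ST]GY"`. For an alignment the
#' scan runs over the consensus sequence of the ungapped reference columns;
#' per-sequence support (the fraction of rows matching the full window) is
#' reported for each hit.
#'
#' @param a an `Alignment` or a plain character sequence.
#' @param pattern motif pattern.
#' @param min_support minimum per-sequence support to report an alignment
#'   hit (default 0: report all consensus matches).
#' @return data.frame with `position` (1-based ungapped position for plain
#'   sequences; reference residue number for alignments), `match` (the
#'   consensus window) and `support`.
#' @export
motif_scan <- function(a, pattern, min_support = 0) {
  toks <- motif_tokens(pattern)
  k <- length(toks)
  if (is.character(a) && length(a) == 1) {
    s <- strsplit(toupper(a), "")[[1]]
    hits <- scan_vector(s, toks)
    return(data.frame(position = hits,
                      match = vapply(hits, function(h)
                        paste(s[h:(h + k - 1)], collapse = ""), ""),
                      support = rep(1, length(hits))))
  }
  stopifnot(inherits(a, "Alignment"))
  prof <- column_profile(a, pseudocount = 0)
  nums <- column_numbers(a)
  cols <- which(!is.na(nums))       # ungapped reference columns
  cons <- prof$consensus[cols]
  hits <- scan_vector(cons, toks)
  if (!length(hits))
    return(data.frame(position = integer(), match = character(),
                      support = numeric()))
  support <- vapply(hits, function(h) {
    win <- a$mat[, cols[h:(h + k - 1)], drop = FALSE]
    mean(apply(win, 1, function(row)
      all(mapply(function(ch, tk) ch %in% tk, row, toks))))
  }, 0)
  out <- data.frame(position = nums[cols[hits]],
                    match = vapply(hits, function(h)
                      paste(cons[h:(h + k - 1)], collapse = ""), ""),
                    support = support)
  out[out$support >= min_support, , drop = FALSE]
}

motif_tokens <- function(pattern) {
  toks <- list()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("motif_scan: unclosed class in pattern")
      toks[[length(toks) + 1]] <- toupper(chars[(i + 1):(j - 1)])
      i <- j + 1
    } else if (ch %in% c("x", "X", ".")) {
      toks[[length(toks) + 1]] <- AA20
      i <- i + 1
    } else {
      toks[[length(toks) + 1]] <- toupper(ch)
      i <- i + 1
    }
  }
  toks
}

scan_vector <- function(s, toks) {
  k <- length(toks)
  if (length(s) < k) return(integer())
  Filter(function(start) all(mapply(function(ch, tk) ch %in% tk,
                                    s[start:(start + k - 1)], toks)),
         seq_len(length(s) - k + 1))
}
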