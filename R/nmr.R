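# Backbone chemical-shift analytics: amide chemical-shift perturbation with
# two-tier significance, secondary chemical shifts versus random coil with
# 1-2-1 smoothing and secondary-structure propensity calls, heteronuclear
# NOE mobility flags, and Gaussian line-shape (FWHM) fitting.

#' Construct a chemical-shift table
#'
#' @param df data.frame with columns `resnum` (strictly increasing integer),
#'   `restype` (1-letter code), and any subset of `H`, `N`, `CA`, `CB`
#'   (ppm; `NA` = unassigned).
#' @return object of class `ShiftTable`.
#' @export
shift_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("resnum", "restype") %in% names(df)))
  for (col in c("H", "N", "CA", "CB"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df$resnum <- as.integer(df$resnum)
  if (is.unsorted(df$resnum, strictly = TRUE))
    stop("shift_table: residue numbers must be strictly increasing")
  for (col in c("H", "N", "CA", "CB"))
    if (any(!is.na(df[[col]]) & !is.finite(df[[col]])))
      stop("shift_table: non-finite shift in column ", col)
  df <- df[, c("resnum", "restype", "H", "N", "CA", "CB")]
  class(df) <- c("ShiftTable", "data.frame")
  df
}

#' Read a chemical-shift table
#'
#' Accepts two dialects: a minimal CSV with header
#' `resnum,restype,H,N,CA,CB` (missing columns allowed), or an
#' NMR-STAR-style whitespace table whose columns include a sequence code,
#' residue label, atom name and shift value (long format, one row per
#' assigned atom: `Comp_index_ID Comp_ID Atom_ID Val` or positional
#' equivalents).
#'
#' @param path file path.
#' @param format `"csv"`, `"star"` or `"auto"`.
#' @return a [shift_table()].
#' @export
read_shift_table <- function(path, format = c("auto", "csv", "star")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (grepl(",", lines[grep("\\S", lines)[1]])) "csv" else "star"
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(shift_table(df))
  }
  body <- lines[grepl("\\S", lines) & !grepl("^[#_]", lines)]
  tab <- utils::read.table(text = body, stringsAsFactors = FALSE)
  # heuristics: first integer column = residue number; residue label is the
  # first 1- or 3-letter amino-acid column; atom name in {H,N,CA,CB};
  # shift = first numeric non-integer column after the atom name
  is_int <- vapply(tab, function(c) is.numeric(c) && all(c == round(c)), TRUE)
  lab_col <- which(vapply(tab, function(c)
    is.character(c) && all(toupper(c) %in% c(names(AA3), AA20)), TRUE))[1]
  # residue number: rightmost integer column left of the residue label
  # (skips a leading row-index column when present)
  cand <- which(is_int)
  resnum_col <- if (!is.na(lab_col) && any(cand < lab_col))
    max(cand[cand < lab_col]) else cand[1]
  atom_col <- which(vapply(tab, function(c)
    is.character(c) && all(toupper(c) %in% c("H", "HN", "N", "CA", "CB")),
    TRUE))[1]
  val_col <- which(vapply(tab, function(c)
    is.numeric(c) && !all(c == round(c)), TRUE))[1]
  if (anyNA(c(resnum_col, lab_col, atom_col, val_col)))
    stop("read_shift_table: cannot identify NMR-STAR-style columns in ", path)
  lab <- toupper(tab[[lab_col]])
  lab1 <- ifelse(nchar(lab) == 3, unname(AA3[lab]), lab)
  atom <- toupper(tab[[atom_col]]); atom[atom == "HN"] <- "H"
  long <- data.frame(resnum = tab[[resnum_col]], restype = lab1,
                     atom = atom, val = tab[[val_col]])
  wide <- data.frame(resnum = sort(unique(long$resnum)))
  wide$restype <- long$restype[match(wide$resnum, long$resnum)]
  for (at in c("H", "N", "CA", "CB")) {
    sub <- long[long$atom == at, ]
    wide[[at]] <- sub$val[match(wide$resnum, sub$resnum)]
  }
  shift_table(wide)
}

#' Amide chemical-shift perturbation (CSP)
#'
#' Computes per residue
#' `dd(HN) = sqrt((dH_ref - dH)^2 + ((dN_ref - dN)/5)^2)` between a
#' reference and a modified shift table, and classifies each residue as
#' `none`, `medium` (`>= t1`) or `strong` (`>= t2`). Residues lacking H or N
#' in either table are marked unassigned.
#'
#' @param ref,mod `ShiftTable`s sharing residue numbering.
#' @param t1,t2 significance thresholds in ppm (defaults 0.2 / 0.4).
#' @param n_scale scaling divisor for the 15N axis (default 5, fixed by the
#'   formula).
#' @return a `CSPProfile`: data.frame `resnum`, `restype`, `dd`, `class`
#'   (factor none < medium < strong, `NA` = unassigned).
#' @export
csp <- function(ref, mod, t1 = 0.2, t2 = 0.4, n_scale = 5) {
  stopifnot(inherits(ref, "ShiftTable"), inherits(mod, "ShiftTable"))
  resnum <- sort(union(ref$resnum, mod$resnum))
  ir <- match(resnum, ref$resnum); im <- match(resnum, mod$resnum)
  ty_r <- ref$restype[ir]; ty_m <- mod$restype[im]
  mism <- !is.na(ty_r) & !is.na(ty_m) & ty_r != ty_m
  if (any(mism))
    warning("csp: residue type mismatch at ",
            paste(resnum[mism], collapse = ", "), " - computed anyway")
  dH <- ref$H[ir] - mod$H[im]
  dN <- (ref$N[ir] - mod$N[im]) / n_scale
  dd <- sqrt(dH^2 + dN^2)
  cls <- rep("none", length(dd))
  cls[dd >= t1] <- "medium"
  cls[dd >= t2] <- "strong"
  cls[is.na(dd)] <- NA
  out <- data.frame(resnum = resnum,
                    restype = ifelse(is.na(ty_r), ty_m, ty_r),
                    dd = dd,
                    class = factor(cls, levels = c("none", "medium",
                                                   "strong"), ordered = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("CSPProfile", "data.frame")
  attr(out, "thresholds") <- c(t1 = t1, t2 = t2)
  out
}

#' Load the bundled random-coil reference shifts
#'
#' Random-coil 13Ca/13Cb values per residue type (ppm), shipped as plain
#' CSV. Values follow the common random-coil compilations used for
#' secondary-shift analysis of intrinsically disordered and folded proteins.
#'
#' @return a `RandomCoilTable`: data.frame `restype`, `CA`, `CB` with all 20
#'   amino acids present.
#' @export
random_coil_table <- function() {
  path <- system.file("extdata", "random_coil_ca_cb.csv",
                      package = "phosphorelay", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_random_coil(tab)
}

validate_random_coil <- function(tab) {
  stopifnot(all(c("restype", "CA", "CB") %in% names(tab)))
  missing <- setdiff(AA20, tab$restype)
  if (length(missing))
    stop("random-coil table lacks residue type(s): ",
         paste(missing, collapse = ", "))
  class(tab) <- c("RandomCoilTable", "data.frame")
  tab
}

#' Combined secondary chemical shifts and propensity calls
#'
#' Per residue, `combined = (dCA - dCA_rc) - (dCB - dCB_rc)` relative to the
#' random-coil reference, smoothed with [smooth_121()]. Glycine has no Cb:
#' its Cb term is set to 0 and the residue is flagged. Propensity calls are
#' made on the smoothed series: runs of at least `helix_run` residues at or
#' above `+threshold` become `helix`, runs of at least `strand_run` residues
#' at or below `-threshold` become `strand`, everything else `coil`.
#'
#' @param t a `ShiftTable`.
#' @param rc a `RandomCoilTable` (default: the bundled one).
#' @param threshold propensity threshold in ppm (default 0.7).
#' @param helix_run,strand_run minimum run lengths (defaults 4 / 3).
#' @return a `SecondaryShiftProfile`: data.frame `resnum`, `restype`, `raw`,
#'   `smoothed`, `propensity`, `gly_flag`.
#' @export
secondary_shifts <- function(t, rc = random_coil_table(), threshold = 0.7,
                             helix_run = 4, strand_run = 3) {
  stopifnot(inherits(t, "ShiftTable"))
  rc <- validate_random_coil(as.data.frame(rc))
  idx <- match(t$restype, rc$restype)
  if (anyNA(idx))
    stop("secondary_shifts: no random-coil entry for residue type ",
         paste(unique(t$restype[is.na(idx)]), collapse = ", "))
  d_ca <- t$CA - rc$CA[idx]
  gly <- t$restype == "G"
  d_cb <- ifelse(gly, 0, t$CB - rc$CB[idx])
  raw <- d_ca - d_cb
  # residues missing Ca (or Cb for non-Gly) stay unassigned gaps
  sm <- smooth_121(raw, positions = t$resnum)
  prop <- rep("coil", length(raw))
  prop[run_mask(sm >= threshold, helix_run)] <- "helix"
  prop[run_mask(sm <= -threshold, strand_run)] <- "strand"
  prop[is.na(sm)] <- NA
  out <- data.frame(resnum = t$resnum, restype = t$restype, raw = raw,
                    smoothed = sm, propensity = prop, gly_flag = gly,
                    stringsAsFactors = FALSE)
  class(out) <- c("SecondaryShiftProfile", "data.frame")
  out
}

run_mask <- function(flag, min_run) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' 1-2-1 smoothing of a per-residue series
#'
#' Interior points become `(x[i-1] + 2 x[i] + x[i+1]) / 4`. At series ends
#' and next to gaps (missing values or breaks in residue numbering) the
#' weights are renormalized over the available neighbours, so an edge point
#' with one neighbour becomes `(2 x[i] + x[nb]) / 3`; gaps stay gaps and
#' values are never mixed across them.
#'
#' @param x numeric series (NA = gap).
#' @param positions optional integer positions; non-consecutive numbering
#'   introduces gaps (default: consecutive).
#' @return smoothed numeric series, same length.
#' @export
smooth_121 <- function(x, positions = seq_along(x)) {
  n <- length(x)
  if (!n) return(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    wsum <- 2; val <- 2 * x[i]
    if (i > 1 && !is.na(x[i - 1]) && positions[i - 1] == positions[i] - 1) {
      val <- val + x[i - 1]; wsum <- wsum + 1
    }
    if (i < n && !is.na(x[i + 1]) && positions[i + 1] == positions[i] + 1) {
      val <- val + x[i + 1]; wsum <- wsum + 1
    }
    out[i] <- val / wsum
  }
  out
}

#' Heteronuclear NOE mobility flags
#'
#' Flags residues whose 15N\{1H\} NOE ratio falls below the threshold as
#' mobile on the ps-ns timescale (e.g. a flexible beta4-beta5 linker shows a
#' dip against a rigid-core background of ~0.8).
#'
#' @param values named or plain numeric vector of HetNOE ratios per residue.
#' @param threshold mobility cutoff (default 0.65).
#' @param resnum optional residue numbers (default names / index).
#' @return data.frame `resnum`, `value`, `mobile`.
#' @export
hetnoe_flags <- function(values, threshold = 0.65, resnum = NULL) {
  out_of_range <- !is.na(values) & (values < -1.5 | values > 1.2)
  if (any(out_of_range))
    warning("hetnoe_flags: ", sum(out_of_range),
            " value(s) outside the plausible ratio range (-1.5, 1.2)")
  resnum <- resnum %||%
    (if (!is.null(names(values))) as.integer(names(values))
     else seq_along(values))
  data.frame(resnum = resnum, value = as.numeric(values),
             mobile = !is.na(values) & values < threshold)
}

#' Fit a Gaussian to a 1-D intensity trace and report the FWHM
#'
#' Least-squares fit of `a * exp(-(x - mu)^2 / (2 sigma^2))` to an intensity
#' trace (e.g. a 1-D slice through an amide resonance); the full width at
#' half-maximal intensity is `2 sqrt(2 ln 2) * sigma ~ 2.3548 sigma` in the
#' units of `x`.
#'
#' @param x positions (e.g. ppm), at least 5 points spanning the peak.
#' @param y intensities.
#' @return list `center`, `fwhm`, `amplitude`, `sigma`, `rss`.
#' @export
gaussian_fwhm <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("gaussian_fwhm: need at least 5 points")
  # moment-based start values
  w <- pmax(y - min(y), 0)
  mu0 <- sum(x * w) / sum(w)
  s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 6
  obj <- function(p) {
    pred <- p[3] * exp(-(x - p[1])^2 / (2 * p[2]^2))
    sum((y - pred)^2)
  }
  fit <- stats::optim(c(mu0, s0, max(y)), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  if (fit$convergence != 0)
    stop("gaussian_fwhm: fit did not converge (residual sum of squares ",
         signif(fit$value, 4), ")")
  sigma <- abs(fit$par[2])
  list(center = fit$par[1], fwhm = 2 * sqrt(2 * log(2)) * sigma,
       amplitude = fit$par[3], sigma = sigma, rss = fit$value)
}
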