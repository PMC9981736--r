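# Macromolecular structure container, PDB/mmCIF io, atom selection,
# crystallographic symmetry expansion and coordinate summaries.

#' Construct a Structure object
#'
#' A `Structure` is the package's in-memory representation of a macromolecular
#' model: a data frame of atom records plus (optionally) the crystallographic
#' unit cell, space-group symbol and symmetry operators.
#'
#' @param atoms data.frame with columns `chain`, `resseq`, `icode`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `bfactor`, `occupancy`, `altloc`.
#'   Missing bookkeeping columns are filled with defaults.
#' @param cell numeric length-6 vector `(a, b, c, alpha, beta, gamma)` in
#'   Angstrom / degrees, or `NULL`.
#' @param spacegroup Hermann-Mauguin symbol (e.g. `"I 1 2 1"`), or `NULL`.
#' @param symops list of 3x4 matrices (fractional rotation | translation);
#'   when `NULL` and the space group is known, operators are looked up from
#'   the bundled table.
#' @param id free-text identifier.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, cell = NULL, spacegroup = NULL,
                          symops = NULL, id = "") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resseq", "icode", "resname", "atom", "element",
            "x", "y", "z", "bfactor", "occupancy", "altloc")
  defaults <- list(chain = "A", resseq = NA_integer_, icode = "",
                   resname = "UNK", atom = "X", element = "",
                   x = NA_real_, y = NA_real_, z = NA_real_,
                   bfactor = 0, occupancy = 1, altloc = "")
  for (col in need) if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$element <- toupper(trimws(atoms$element))
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- guess_element(atoms$atom[blank])
  atoms$is_water <- atoms$resname %in% WATER_RESNAMES
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("Structure: all atom coordinates must be finite")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("Structure: occupancy must lie in [0, 1]")
  if (any(atoms$bfactor < 0, na.rm = TRUE))
    stop("Structure: B-factors must be non-negative")
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom, atoms$altloc)
  if (anyDuplicated(key))
    stop("Structure: duplicated (chain, resseq, icode, atom, altloc) record: ",
         key[duplicated(key)][1])
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    stopifnot(length(cell) == 6)
    if (any(cell[1:3] <= 0)) stop("Structure: cell lengths must be positive")
  }
  if (is.null(symops) && !is.null(spacegroup))
    symops <- tryCatch(spacegroup_operators(spacegroup), error = function(e) NULL)
  structure(list(atoms = atoms, cell = cell, spacegroup = spacegroup,
                 symops = symops, id = id),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d atoms, %d chains",
              x$id, nrow(x$atoms), length(unique(x$atoms$chain))))
  if (!is.null(x$cell))
    cat(sprintf("; cell %.1f %.1f %.1f A, '%s'", x$cell[1], x$cell[2],
                x$cell[3], x$spacegroup %||% "?"))
  cat("\n")
  invisible(x)
}

guess_element <- function(atom_names) {
  nm <- toupper(trimws(atom_names))
  el <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  two <- substr(gsub("[^A-Z]", "", nm), 1, 2)
  el[two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA")]
  # distance geometry atoms like "1HB" start with a digit -> hydrogen
  el[grepl("^[0-9]*H", nm)] <- "H"
  el
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' All ATOM/HETATM records are retained (including alternate locations);
#' author residue numbering is preserved as the canonical numbering. The unit
#' cell, space-group symbol and any symmetry operators present in the file
#' (PDB `REMARK 290 SMTRY` or mmCIF `_symmetry_equiv_pos_as_xyz`) are
#' captured; otherwise operators are looked up from a bundled table of common
#' settings (including `I 1 2 1`).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension, default).
#' @return a [new_structure()] `Structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE))
      "pdb" else stop("read_structure: cannot infer format of ", path,
                      " - pass format explicitly")
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") parse_pdb(lines, id = basename(path))
  else parse_mmcif(lines, id = basename(path))
}

parse_pdb <- function(lines, id = "") {
  rec <- substr(lines, 1, 6)
  at <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(at)) stop("PDB parse error: no ATOM/HETATM records found")
  al <- lines[at]
  num <- function(s, a, b) {
    v <- suppressWarnings(as.numeric(substr(s, a, b)))
    v
  }
  x <- num(al, 31, 38); y <- num(al, 39, 46); z <- num(al, 47, 54)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("PDB parse error at line ", at[bad[1]], ": unreadable coordinates")
  occ <- num(al, 55, 60); occ[!is.finite(occ)] <- 1
  bf <- num(al, 61, 66); bf[!is.finite(bf)] <- 0
  atoms <- data.frame(
    chain = trimws(substr(al, 22, 22)),
    resseq = as.integer(num(al, 23, 26)),
    icode = trimws(substr(al, 27, 27)),
    resname = trimws(substr(al, 18, 20)),
    atom = trimws(substr(al, 13, 16)),
    element = trimws(substr(al, 77, 78)),
    x = x, y = y, z = z, bfactor = bf, occupancy = occ,
    altloc = trimws(substr(al, 17, 17)),
    stringsAsFactors = FALSE)
  cell <- NULL; sg <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    cr <- cr[1]
    cell <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                         substr(cr, 25, 33), substr(cr, 34, 40),
                         substr(cr, 41, 47), substr(cr, 48, 54)))
    sg <- trimws(substr(cr, 56, 66))
  }
  symops <- parse_remark290(lines)
  new_structure(atoms, cell = cell, spacegroup = sg, symops = symops, id = id)
}

parse_remark290 <- function(lines) {
  sm <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (!length(sm)) return(NULL)
  f <- do.call(rbind, lapply(sm, function(l) {
    v <- scan(text = substr(l, 20, nchar(l)), quiet = TRUE)
    v  # opnum, r1, r2, r3, t
  }))
  ops <- split(as.data.frame(f), f[, 1])
  lapply(unname(ops), function(d) {
    m <- as.matrix(d[, 2:5])
    dimnames(m) <- NULL
    m  # 3 x 4
  })
}

parse_mmcif <- function(lines, id = "") {
  # minimal tokenizer for the atom_site loop + cell/symmetry items
  lines <- sub("\r$", "", lines)
  get_item <- function(tag) {
    hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", hit[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  loop_start <- which(lines == "loop_")
  atom_block <- NULL
  for (ls in loop_start) {
    j <- ls + 1
    hdr <- character()
    while (j <= length(lines) && grepl("^_", lines[j])) {
      hdr <- c(hdr, trimws(lines[j])); j <- j + 1
    }
    if (any(grepl("^_atom_site\\.", hdr))) {
      k <- j
      while (k <= length(lines) && !grepl("^(loop_|_|#)", lines[k]) &&
             nzchar(trimws(lines[k]))) k <- k + 1
      atom_block <- list(hdr = hdr, body = lines[j:(k - 1)])
      break
    }
  }
  if (is.null(atom_block))
    stop("mmCIF parse error: no _atom_site loop found")
  hdr <- sub("^_atom_site\\.", "", atom_block$hdr)
  con <- textConnection(atom_block$body)
  on.exit(close(con))
  tab <- utils::read.table(con, stringsAsFactors = FALSE,
                           col.names = hdr, fill = TRUE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    NULL
  }
  unq <- function(v) if (is.character(v)) gsub("^['\"]|['\"]$", "", v) else v
  clean <- function(v, def) {
    if (is.null(v)) return(def)
    v <- unq(v); v[v %in% c(".", "?")] <- def; v
  }
  atoms <- data.frame(
    chain = clean(pick("auth_asym_id", "label_asym_id"), "A"),
    resseq = as.integer(clean(pick("auth_seq_id", "label_seq_id"), NA)),
    icode = clean(pick("pdbx_PDB_ins_code"), ""),
    resname = clean(pick("auth_comp_id", "label_comp_id"), "UNK"),
    atom = clean(pick("auth_atom_id", "label_atom_id"), "X"),
    element = clean(pick("type_symbol"), ""),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    bfactor = as.numeric(clean(pick("B_iso_or_equiv"), "0")),
    occupancy = as.numeric(clean(pick("occupancy"), "1")),
    altloc = clean(pick("label_alt_id"), ""),
    stringsAsFactors = FALSE)
  cell <- c(get_item("_cell.length_a"), get_item("_cell.length_b"),
            get_item("_cell.length_c"), get_item("_cell.angle_alpha"),
            get_item("_cell.angle_beta"), get_item("_cell.angle_gamma"))
  cell <- if (all(!vapply(cell, is.null, TRUE))) as.numeric(cell) else NULL
  sg <- get_item("_symmetry.space_group_name_H-M") %||%
    get_item("_space_group.name_H-M_alt")
  symops <- parse_mmcif_symops(lines)
  new_structure(atoms, cell = cell, spacegroup = sg, symops = symops, id = id)
}

parse_mmcif_symops <- function(lines) {
  hit <- grep("_symmetry_equiv\\.?_?pos_as_xyz|_space_group_symop", lines)
  if (!length(hit)) return(NULL)
  xyz <- regmatches(lines, regexpr("['\"][^'\"]*[XxYyZz][^'\"]*['\"]", lines))
  xyz <- gsub("^['\"]|['\"]$", "", xyz)
  xyz <- xyz[grepl(",", xyz)]
  if (!length(xyz)) return(NULL)
  lapply(xyz, parse_symop_xyz)
}

#' Write a Structure to a PDB file
#'
#' @param s a `Structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  out <- character()
  if (!is.null(s$cell))
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                          s$cell[1], s$cell[2], s$cell[3], s$cell[4],
                          s$cell[5], s$cell[6], s$spacegroup %||% "P 1"))
  aname <- ifelse(nchar(a$atom) <= 3 & !grepl("^[0-9]", a$atom),
                  sprintf(" %-3s", a$atom), sprintf("%-4s", a$atom))
  rec <- ifelse(a$is_water | !(a$resname %in% names(AA3)), "HETATM", "ATOM  ")
  out <- c(out, sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)) %% 100000L, aname, a$altloc, a$resname, a$chain,
    a$resseq, ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occupancy, a$bfactor, a$element), "END")
  writeLines(out, path)
  invisible(path)
}

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

#' Describe an atom selection
#'
#' @param chains optional character vector of chain ids.
#' @param residue_ranges optional list of inclusive `c(start, end)` pairs in
#'   author numbering, or a single such pair.
#' @param atom_class one of `"all-heavy"`, `"CA"`, `"mainchain+CB"`,
#'   `"sidechain"`.
#' @param exclude_water,exclude_hydrogen logical, default `TRUE`.
#' @param altloc_policy `"highest-occupancy"` (ties broken towards label
#'   `"A"`; the default) or `"first"`.
#' @return a `Selection` object.
#' @export
atom_selection <- function(chains = NULL, residue_ranges = NULL,
                           atom_class = c("all-heavy", "CA", "mainchain+CB",
                                          "sidechain"),
                           exclude_water = TRUE, exclude_hydrogen = TRUE,
                           altloc_policy = c("highest-occupancy", "first")) {
  atom_class <- match.arg(atom_class)
  altloc_policy <- match.arg(altloc_policy)
  if (!is.null(residue_ranges)) {
    if (!is.list(residue_ranges)) residue_ranges <- list(residue_ranges)
    for (rr in residue_ranges) {
      stopifnot(length(rr) == 2)
      if (rr[1] > rr[2]) stop("atom_selection: ill-ordered residue range")
    }
  }
  structure(list(chains = chains, residue_ranges = residue_ranges,
                 atom_class = atom_class, exclude_water = exclude_water,
                 exclude_hydrogen = exclude_hydrogen,
                 altloc_policy = altloc_policy),
            class = "Selection")
}

#' Select atoms from a Structure
#'
#' Applies all clauses of a [atom_selection()] and resolves alternate
#' locations to a single conformer per atom according to the selection's
#' `altloc_policy`. Rows are returned in stable
#' (chain, resseq, icode, atom) order.
#'
#' @param s a `Structure`.
#' @param sel a `Selection` (default: all heavy non-water atoms).
#' @return data.frame of atom records.
#' @export
select_atoms <- function(s, sel = atom_selection()) {
  stopifnot(inherits(s, "Structure"), inherits(sel, "Selection"))
  a <- s$atoms
  if (sel$exclude_water) a <- a[!a$is_water, , drop = FALSE]
  if (sel$exclude_hydrogen) a <- a[!a$is_hydrogen, , drop = FALSE]
  if (!is.null(sel$chains)) a <- a[a$chain %in% sel$chains, , drop = FALSE]
  if (!is.null(sel$residue_ranges)) {
    keep <- rep(FALSE, nrow(a))
    for (rr in sel$residue_ranges)
      keep <- keep | (a$resseq >= rr[1] & a$resseq <= rr[2])
    if (!any(keep))
      warning("select_atoms: residue ranges match no residues")
    a <- a[keep, , drop = FALSE]
  }
  a <- switch(sel$atom_class,
    "all-heavy" = a,
    "CA" = a[a$atom == "CA", , drop = FALSE],
    "mainchain+CB" = a[a$atom %in% c(MAINCHAIN_ATOMS, "CB"), , drop = FALSE],
    "sidechain" = a[!(a$atom %in% c(MAINCHAIN_ATOMS, "OXT")), , drop = FALSE])
  a <- resolve_altlocs(a, sel$altloc_policy)
  a[order(a$chain, a$resseq, a$icode, a$atom), , drop = FALSE]
}

resolve_altlocs <- function(a, policy) {
  if (!nrow(a) || all(a$altloc == "")) return(a)
  key <- paste(a$chain, a$resseq, a$icode, a$atom)
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    if (policy == "first") return(idx[1])
    occ <- a$occupancy[idx]
    best <- idx[occ == max(occ)]
    # ties: lowest altloc label wins (label 'A' preferred)
    best[order(a$altloc[best])][1]
  }), use.names = FALSE)
  a[sort(keep), , drop = FALSE]
}

#' Summarize a Structure (atom counts, mean B-factors, cell)
#'
#' Protein atoms are heavy atoms of standard amino-acid residues; waters are
#' counted separately. Every deposited record is counted once, so alternate
#' conformers contribute each of their copies (`n_protein_atoms_unique` gives
#' the altloc-deduplicated count). Mean B-factors are arithmetic means over
#' the counted atoms.
#'
#' @param s a `Structure`.
#' @return list of class `StructureSummary`.
#' @export
summarize_structure <- function(s) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms[!s$atoms$is_hydrogen, , drop = FALSE]
  prot <- a[a$resname %in% names(AA3), , drop = FALSE]
  wat <- a[a$is_water, , drop = FALSE]
  uniq <- if (nrow(prot))
    nrow(unique(prot[, c("chain", "resseq", "icode", "atom")])) else 0L
  out <- list(
    n_protein_atoms = nrow(prot),
    n_protein_atoms_unique = uniq,
    n_water = nrow(wat),
    mean_b_protein = if (nrow(prot)) mean(prot$bfactor) else NA_real_,
    mean_b_water = if (nrow(wat)) mean(wat$bfactor) else NA_real_,
    cell = s$cell, spacegroup = s$spacegroup, id = s$id)
  class(out) <- "StructureSummary"
  out
}

#' @export
print.StructureSummary <- function(x, ...) {
  cat(sprintf("StructureSummary '%s'\n", x$id))
  cat(sprintf("  protein atoms: %d (unique sites %d)  waters: %d\n",
              x$n_protein_atoms, x$n_protein_atoms_unique, x$n_water))
  cat(sprintf("  <B> protein: %s  <B> water: %s\n",
              if (is.na(x$mean_b_protein)) "-" else
                sprintf("%.1f", x$mean_b_protein),
              if (is.na(x$mean_b_water)) "-" else
                sprintf("%.1f", x$mean_b_water)))
  if (!is.null(x$cell))
    cat(sprintf("  cell: %.1f %.1f %.1f / %.1f %.1f %.1f  '%s'\n",
                x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5],
                x$cell[6], x$spacegroup %||% "?"))
  invisible(x)
}

# ---- crystallographic symmetry ------------------------------------------

#' Parse a symmetry operator in xyz notation
#'
#' Turns e.g. `"-X,Y+1/2,-Z"` into a 3x4 matrix of fractional rotation and
#' translation.
#' @param txt operator string.
#' @return 3x4 numeric matrix.
#' @export
parse_symop_xyz <- function(txt) {
  parts <- strsplit(toupper(gsub("\\s", "", txt)), ",")[[1]]
  if (length(parts) != 3) stop("parse_symop_xyz: need 3 components in ", txt)
  m <- matrix(0, 3, 4)
  for (i in 1:3) {
    p <- parts[i]
    # tokenize into signed terms
    terms <- regmatches(p, gregexpr("[+-]?[^+-]+", p))[[1]]
    for (tm in terms) {
      sgn <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("X", "Y", "Z")) {
        m[i, match(body, c("X", "Y", "Z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        fr <- as.numeric(strsplit(body, "/")[[1]])
        m[i, 4] <- m[i, 4] + sgn * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", body)) {
        m[i, 4] <- m[i, 4] + sgn * as.numeric(body)
      } else stop("parse_symop_xyz: cannot parse term '", tm, "'")
    }
  }
  m
}

# operators for common space-group settings, in xyz notation
SPACEGROUP_XYZ <- list(
  "P 1" = c("X,Y,Z"),
  "P 1 2 1" = c("X,Y,Z", "-X,Y,-Z"),
  "P 1 21 1" = c("X,Y,Z", "-X,Y+1/2,-Z"),
  "C 1 2 1" = c("X,Y,Z", "-X,Y,-Z",
                "X+1/2,Y+1/2,Z", "-X+1/2,Y+1/2,-Z"),
  "I 1 2 1" = c("X,Y,Z", "-X,Y,-Z",
                "X+1/2,Y+1/2,Z+1/2", "-X+1/2,Y+1/2,-Z+1/2"),
  "P 21 21 21" = c("X,Y,Z", "-X+1/2,-Y,Z+1/2",
                   "-X,Y+1/2,-Z+1/2", "X+1/2,-Y+1/2,-Z"),
  "P 2 2 2" = c("X,Y,Z", "-X,-Y,Z", "-X,Y,-Z", "X,-Y,-Z")
)

#' Symmetry operators for a space-group symbol
#'
#' Looks the Hermann-Mauguin symbol up in the bundled operator table.
#' @param symbol e.g. `"I 1 2 1"`; whitespace-insensitive.
#' @return list of 3x4 fractional operator matrices.
#' @export
spacegroup_operators <- function(symbol) {
  key <- toupper(trimws(symbol))
  hit <- which(vapply(names(SPACEGROUP_XYZ),
                      function(n) gsub(" ", "", n) == gsub(" ", "", key), TRUE))
  if (!length(hit))
    stop("spacegroup_operators: no bundled operators for '", symbol, "'")
  lapply(SPACEGROUP_XYZ[[hit[1]]], parse_symop_xyz)
}

# orthogonalization matrix (fractional -> cartesian) for a unit cell
orthogonalization_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)), nrow = 3, byrow = TRUE)
}

#' Generate contacting crystal symmetry mates
#'
#' Applies every space-group operator combined with lattice translations and
#' returns each non-identity copy that has at least one atom within `radius`
#' of the input copy.
#'
#' @param s a `Structure` with cell and symmetry operators.
#' @param radius contact radius in Angstrom.
#' @return list of `list(label, structure)`; `label` encodes the operator
#'   index and lattice shift, e.g. `"op2+(1,0,-1)"`.
#' @export
expand_symmetry <- function(s, radius) {
  stopifnot(inherits(s, "Structure"))
  if (is.null(s$cell) || is.null(s$symops))
    stop("expand_symmetry: structure lacks cell or symmetry operators")
  if (radius <= 0) return(list())
  O <- orthogonalization_matrix(s$cell)
  Oinv <- solve(O)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  frac <- xyz %*% t(Oinv)
  # lattice search range wide enough for the contact radius
  nmax <- pmax(1L, ceiling(radius / s$cell[1:3]) + 1L)
  shifts <- expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2],
                        k = -nmax[3]:nmax[3])
  out <- list()
  for (oi in seq_along(s$symops)) {
    op <- s$symops[[oi]]
    R <- op[, 1:3, drop = FALSE]; tt <- op[, 4]
    base <- frac %*% t(R)
    for (si in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[si, ])
      is_ident <- oi == 1L && all(sh == 0) &&
        all(abs(R - diag(3)) < 1e-9) && all(abs(tt) < 1e-9)
      if (is_ident) next
      f2 <- sweep(base, 2, tt + sh, "+")
      c2 <- f2 %*% t(O)
      # bounding-box prefilter before the full distance check
      if (any(apply(c2, 2, min) > apply(xyz, 2, max) + radius) ||
          any(apply(c2, 2, max) < apply(xyz, 2, min) - radius)) next
      if (min_cross_dist(xyz, c2) >= radius) next
      s2 <- s
      s2$atoms$x <- c2[, 1]; s2$atoms$y <- c2[, 2]; s2$atoms$z <- c2[, 3]
      s2$id <- sprintf("%s op%d+(%d,%d,%d)", s$id, oi, sh[1], sh[2], sh[3])
      out[[length(out) + 1L]] <- list(
        label = sprintf("op%d+(%d,%d,%d)", oi, sh[1], sh[2], sh[3]),
        structure = s2)
    }
  }
  out
}

# one-letter sequence + residue table of the CA trace of a selection
ca_trace <- function(s, sel = atom_selection(atom_class = "CA")) {
  sel$atom_class <- "CA"
  ca <- select_atoms(s, sel)
  ca$aa1 <- unname(AA3[ca$resname])
  ca$aa1[is.na(ca$aa1)] <- "X"
  ca
}
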