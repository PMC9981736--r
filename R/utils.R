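# Shared constants and small helpers.

#' @keywords internal
"_PACKAGE"

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA1 <- names(AA3)
names(AA1) <- unname(AA3)

AA20 <- sort(unname(AA3))  # fixed amino-acid order for all tables

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# van der Waals radii (Angstrom); fallback handled by callers
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, D = 1.20, SE = 1.90, F = 1.47, CL = 1.75,
               BR = 1.85, I = 1.98, MG = 1.73, ZN = 1.39, FE = 1.40,
               MN = 1.39, CA = 2.00, "NA" = 2.27, K = 2.75, BE = 1.53)

#' Run code with a deterministic, generator-scoped random stream
#'
#' Derives an integer seed from `(seed, name)` so that each generator has its
#' own stream and adding generators does not shift existing fixtures. Restores
#' the caller's RNG state on exit.
#' @param seed integer master seed
#' @param name character scope label (usually the generator name)
#' @param code code to evaluate under the derived seed
#' @keywords internal
with_scoped_seed <- function(seed, name, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  derived <- (abs(as.integer(seed)) %% 65011L) * 33013L +
    (sum(utf8ToInt(name)) %% 33013L)
  derived <- as.integer(derived %% 2147483647L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derived)
  force(code)
}

# Euclidean min distance between two coordinate matrices (n x 3, m x 3).
min_cross_dist <- function(a, b) {
  sqrt(min(cross_dist2(a, b)))
}

# Squared distance matrix between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Random rotation matrix (uniform over SO(3)) from the current RNG stream.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
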