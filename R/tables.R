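# Embedded constant tables used by the sequence encoders.

#' @keywords internal
NT_BASES <- c("A", "C", "G", "T")

#' @keywords internal
NT_ALPHABET <- c("A", "C", "G", "T", "N")

# Canonical 20 residues in the fixed encoder order.
#' @keywords internal
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Fickett (1982) TESTCODE lookup tables. Each statistic is mapped to the
# probability of the first bin whose lower bound it reaches (bins scanned
# from the highest threshold down; the final threshold 0 catches everything).
# Position statistic = MAX(frame counts)/(MIN(frame counts)+1); content
# statistic = base fraction of the whole sequence.
FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)

FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)

FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.35, 0.31, 0.17, 0.20),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

# Chou pseudo-amino-acid-composition property tables: hydrophobicity
# (Tanford scale), hydrophilicity (Hopp-Woods) and side-chain mass.
# Standardized (mean 0, sd 1 over the 20 residues) before use.
AA_HYDROPHOBICITY <- c(
  A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
  I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
  R = -2.53, S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26
)
AA_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
  I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
  R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3
)
AA_SIDECHAIN_MASS <- c(
  A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0, G = 1.0, H = 82.0,
  I = 57.0, K = 73.0, L = 57.0, M = 75.0, N = 58.0, P = 42.0, Q = 72.0,
  R = 101.0, S = 31.0, T = 45.0, V = 43.0, W = 130.0, Y = 107.0
)

#' Standardized residue property tables
#'
#' Returns the three Chou pseudo-amino-acid-composition property tables
#' (hydrophobicity, hydrophilicity, side-chain mass), each standardized to
#' zero mean and unit (population) standard deviation over the 20 canonical
#' residues, in `ACDEFGHIKLMNPQRSTVWY` order.
#'
#' @return A named list of three numeric vectors of length 20.
#' @export
aa_property_tables <- function() {
  std <- function(x) {
    x <- x[AA_ALPHABET]
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  }
  list(
    hydrophobicity = std(AA_HYDROPHOBICITY),
    hydrophilicity = std(AA_HYDROPHILICITY),
    side_chain_mass = std(AA_SIDECHAIN_MASS)
  )
}

#' Residue-pair distance matrices for quasi-sequence-order descriptors
#'
#' Builds the two 20 x 20 symmetric, zero-diagonal residue distance matrices
#' used by [qsorder()]. Both are synthetic stand-ins derived from the
#' standardized property tables (the classical physicochemical and chemical
#' distance constants are not bundled): `physicochemical` is the Euclidean
#' distance over (hydrophobicity, hydrophilicity); `chemical` is the
#' Euclidean distance over (side-chain mass, hydrophobicity). Each matrix is
#' scaled so its largest entry is 1.
#'
#' @return Named list of two 20 x 20 matrices with dimnames the residues.
#' @export
aa_distance_matrices <- function() {
  p <- aa_property_tables()
  dmat <- function(cols) {
    m <- as.matrix(stats::dist(do.call(cbind, cols)))
    dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
    m / max(m)
  }
  list(
    physicochemical = dmat(p[c("hydrophobicity", "hydrophilicity")]),
    chemical = dmat(p[c("side_chain_mass", "hydrophobicity")])
  )
}
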