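#' Amino-acid alphabets and residue classes
#'
#' `AA_ALPHABET` is the 20 standard amino-acid one-letter codes in
#' alphabetical order. `AA_SMALL` (A, D, G, N, P, S) and `AA_BULKY`
#' (F, H, K, R, Y) are the small and bulky residue classes used for
#' length-resolved usage analysis; the remaining nine residues belong to
#' neither class.
#'
#' @format Character vectors of one-letter residue codes.
#' @name amino_acid_sets
NULL

#' @rdname amino_acid_sets
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname amino_acid_sets
#' @export
AA_SMALL <- c("A", "D", "G", "N", "P", "S")

#' @rdname amino_acid_sets
#' @export
AA_BULKY <- c("F", "H", "K", "R", "Y")

# Physicochemical property scales used to build the synthetic similarity
# matrix: Kyte-Doolittle hydropathy, residue volume (A^3), Grantham
# polarity, net side-chain charge at pH 7.
aa_properties <- function() {
  m <- rbind(
    hydropathy = c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
                   G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
                   M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3),
    volume     = c(A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
                   G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
                   M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
                   S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6),
    polarity   = c(A =  8.1, C =  5.5, D = 13.0, E = 12.3, F =  5.2,
                   G =  9.0, H = 10.4, I =  5.2, K = 11.3, L =  4.9,
                   M =  5.7, N = 11.6, P =  8.0, Q = 10.5, R = 10.5,
                   S =  9.2, T =  8.6, V =  5.9, W =  5.4, Y =  6.2),
    charge     = c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1,
                   I = 0, K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0,
                   R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0)
  )
  m[, AA_ALPHABET]
}

#' Synthetic PMBEC-style amino-acid similarity matrix
#'
#' Builds a symmetric 20x20 similarity matrix from standard physicochemical
#' property scales (hydropathy, volume, polarity, charge): each property is
#' standardised, and similarity is a Gaussian kernel on Euclidean property
#' distance. The diagonal is strictly the maximum of every row (self-identity
#' scores 1), the property a pocket-homology scorer relies on. This matrix is
#' a synthetic stand-in with the same structural properties as experimentally
#' derived substitution-similarity matrices such as PMBEC; a real PMBEC file
#' can be supplied to [read_similarity_matrix()] instead.
#'
#' @param bandwidth Kernel bandwidth on the standardised property distance.
#'   Smaller values sharpen the distinction between similar and dissimilar
#'   residues. Default 2.
#' @return A 20x20 numeric matrix with residue letters as dimnames.
#' @export
#' @examples
#' M <- synthetic_similarity_matrix()
#' all(diag(M) == 1)
synthetic_similarity_matrix <- function(bandwidth = 2) {
  props <- aa_properties()
  z <- t(scale(t(props)))
  d <- as.matrix(stats::dist(t(z)))
  M <- exp(-(d^2) / (2 * bandwidth^2))
  dimnames(M) <- list(AA_ALPHABET, AA_ALPHABET)
  round((M + t(M)) / 2, 6)
}

#' Uniform contact weights for a set of pocket positions
#'
#' Contact-probability weights express how likely each pocket residue is to
#' contact the peptide binding region; they scale each position's
#' contribution to the pocket homology score. When no structure-derived
#' weights are available a uniform weight of 1 at every position is the
#' neutral default.
#'
#' @param positions Integer vector of reference-numbered residue positions.
#' @param weight Single weight in `[0, 1]` applied to every position.
#' @return A tibble with columns `position`, `weight`.
#' @export
uniform_contact_weights <- function(positions, weight = 1) {
  stopifnot(all(positions >= 1), weight >= 0, weight <= 1)
  tibble(position = as.integer(sort(unique(positions))), weight = weight)
}
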