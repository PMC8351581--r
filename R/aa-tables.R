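# Canonical amino-acid order used for every indexed feature vector.
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.aa_index <- stats::setNames(seq_along(AA), AA)

# Five physicochemical residue groups (grouped pair/triad descriptors).
AA_GROUPS5 <- list(
  ali = c("G", "A", "V", "L", "M", "I"),   # aliphatic
  aro = c("F", "Y", "W"),                  # aromatic
  pos = c("K", "R", "H"),                  # positively charged
  neg = c("D", "E"),                       # negatively charged
  unc = c("S", "T", "C", "P", "N", "Q")    # uncharged polar
)

# Seven conjoint-triad classes (Shen et al. grouping by dipole/volume).
AA_CONJOINT7 <- list(
  c1 = c("A", "G", "V"),
  c2 = c("I", "L", "F", "P"),
  c3 = c("Y", "M", "T", "S"),
  c4 = c("H", "N", "Q", "W"),
  c5 = c("R", "K"),
  c6 = c("D", "E"),
  c7 = c("C")
)

# Seven CTD properties, each a 3-group partition of the alphabet
# (Dubchak's composition/transition/distribution encoding).
CTD_PROPERTIES <- list(
  hydrophobicity = list(g1 = strsplit("RKEDQN", "")[[1]],
                        g2 = strsplit("GASTPHY", "")[[1]],
                        g3 = strsplit("CLVIMFW", "")[[1]]),
  vdwvolume      = list(g1 = strsplit("GASTPDC", "")[[1]],
                        g2 = strsplit("NVEQIL", "")[[1]],
                        g3 = strsplit("MHKFRYW", "")[[1]]),
  polarity       = list(g1 = strsplit("LIFWCMVY", "")[[1]],
                        g2 = strsplit("PATGS", "")[[1]],
                        g3 = strsplit("HQRKNED", "")[[1]]),
  polarizability = list(g1 = strsplit("GASDT", "")[[1]],
                        g2 = strsplit("CPNVEQIL", "")[[1]],
                        g3 = strsplit("KMHFRYW", "")[[1]]),
  charge         = list(g1 = strsplit("KR", "")[[1]],
                        g2 = strsplit("ANCQGHILMFPSTWYV", "")[[1]],
                        g3 = strsplit("DE", "")[[1]]),
  secondarystruct = list(g1 = strsplit("EALMQKRH", "")[[1]],
                         g2 = strsplit("VIYCWFT", "")[[1]],
                         g3 = strsplit("GNPSD", "")[[1]]),
  solventaccess  = list(g1 = strsplit("ALFCGIVW", "")[[1]],
                        g2 = strsplit("RKQEND", "")[[1]],
                        g3 = strsplit("MSPTHY", "")[[1]])
)

# Eight published residue scales used by the autocorrelation descriptors
# (z-scored over the 20 residues before lagging). Order follows AA.
AA_AUTOCORR_PROPS <- local({
  m <- rbind(
    hydropathy = c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                   W = -0.9, Y = -1.3),
    hydrophilicity = c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
                       H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
                       P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
                       W = -3.4, Y = -2.3),
    polarity = c(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0,
                 H = 10.4, I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6,
                 P = 8.0, Q = 10.5, R = 10.5, S = 9.2, T = 8.6, V = 5.9,
                 W = 5.4, Y = 6.2),
    volume = c(A = 31, C = 55, D = 54, E = 83, F = 132, G = 3,
               H = 96, I = 111, K = 119, L = 111, M = 105, N = 56,
               P = 32.5, Q = 85, R = 124, S = 32, T = 61, V = 84,
               W = 170, Y = 136),
    isoelectric = c(A = 6.00, C = 5.07, D = 2.77, E = 3.22, F = 5.48, G = 5.97,
                    H = 7.59, I = 6.02, K = 9.74, L = 5.98, M = 5.74, N = 5.41,
                    P = 6.30, Q = 5.65, R = 10.76, S = 5.68, T = 5.60, V = 5.96,
                    W = 5.89, Y = 5.66),
    helix = c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57,
              H = 1.00, I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67,
              P = 0.57, Q = 1.11, R = 0.98, S = 0.77, T = 0.83, V = 1.06,
              W = 1.08, Y = 0.69),
    sheet = c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75,
              H = 0.87, I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89,
              P = 0.55, Q = 1.10, R = 0.93, S = 0.75, T = 1.19, V = 1.70,
              W = 1.37, Y = 1.47),
    mass = c(A = 71.08, C = 103.14, D = 115.09, E = 129.12, F = 147.18,
             G = 57.05, H = 137.14, I = 113.16, K = 128.17, L = 113.16,
             M = 131.19, N = 114.10, P = 97.12, Q = 128.13, R = 156.19,
             S = 87.08, T = 101.10, V = 99.13, W = 186.21, Y = 163.18)
  )
  m[, AA]
})

# Three residue scales of the pseudo amino-acid compositions:
# hydrophobicity (Eisenberg consensus), hydrophilicity (Hopp-Woods),
# side-chain mass. Standardized over the 20 residues before use.
AA_PAAC_PROPS <- local({
  m <- rbind(
    h1 = c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
           H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
           P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
           W = 0.81, Y = 0.26),
    h2 = c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
           H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
           P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
           W = -3.4, Y = -2.3),
    mass = c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1,
             H = 82, I = 57, K = 73, L = 57, M = 75, N = 58,
             P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
             W = 130, Y = 107)
  )
  m[, AA]
})

# Grantham's side-chain composition, polarity and volume; the chemical
# distance matrix is computed from his published formula.
.grantham_c <- c(A = 0, C = 2.75, D = 1.38, E = 0.92, F = 0, G = 0.74,
                 H = 0.58, I = 0, K = 0.33, L = 0, M = 0, N = 1.33,
                 P = 0.39, Q = 0.89, R = 0.65, S = 1.42, T = 0.71, V = 0,
                 W = 0.13, Y = 0.20)[AA]
.grantham_p <- AA_AUTOCORR_PROPS["polarity", ]
.grantham_v <- AA_AUTOCORR_PROPS["volume", ]

#' @noRd
grantham_distance_matrix <- function() {
  d <- 50.723 * sqrt(1.833   * outer(.grantham_c, .grantham_c, "-")^2 +
                     0.1018  * outer(.grantham_p, .grantham_p, "-")^2 +
                     0.000399 * outer(.grantham_v, .grantham_v, "-")^2)
  dimnames(d) <- list(AA, AA)
  d
}

# Physicochemical residue distance: root mean squared difference of the
# three standardized pseudo-composition properties.
#' @noRd
pcd_distance_matrix <- function() {
  z <- t(apply(AA_PAAC_PROPS, 1, function(x) (x - mean(x)) / stats::sd(x)))
  d <- sqrt((outer(z[1, ], z[1, ], "-")^2 +
             outer(z[2, ], z[2, ], "-")^2 +
             outer(z[3, ], z[3, ], "-")^2) / 3)
  dimnames(d) <- list(AA, AA)
  d
}

# Number of codons per amino acid (standard genetic code), for the
# dipeptide-deviation-from-expectation descriptor. Sum = 61.
AA_CODON_COUNTS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                     K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                     T = 4, V = 4, W = 1, Y = 2)[AA]

#' @noRd
aa_to_index <- function(sequence) {
  idx <- .aa_index[strsplit(sequence, "", fixed = TRUE)[[1]]]
  if (anyNA(idx)) {
    stop("sequence contains non-canonical residues; sanitize first")
  }
  unname(idx)
}

#' @noRd
group_map <- function(groups) {
  map <- integer(20)
  names(map) <- AA
  for (g in seq_along(groups)) map[groups[[g]]] <- g
  map
}
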