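# Grantham (1974) physicochemical side-chain properties.
# c: composition (atomic weight ratio of hetero elements to carbon),
# p: polarity, v: molecular volume. Values identical to AAindex
# GRAR740101/02/03.
grantham_properties <- function() {
  data.frame(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE)
}

#' The Grantham substitution-distance model
#'
#' Physicochemical dissimilarity between amino acids built from three
#' side-chain properties — composition (c), polarity (p) and molecular
#' volume (v): for residues i, j,
#' \deqn{D_{ij} = \rho \sqrt{\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 +
#'   \gamma (v_i-v_j)^2}}
#' with \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018}, \eqn{\gamma = 0.000399}
#' (the squared reciprocals of the mean pairwise property differences) and
#' \eqn{\rho} the constant scaling the mean of the 190 inter-residue
#' distances to 100. Larger distances mean more radical substitutions; the
#' scale runs from 5 (Leu/Ile) to 215 (Cys/Trp).
#'
#' Note that the historical integer table reprinted across the literature
#' wobbles by one unit around this formula for a few pairs (its rounding is
#' internally inconsistent: no single \eqn{\rho} reproduces every printed
#' entry). This package always computes from the model in full precision and
#' rounds only for reporting.
#'
#' @param alpha,beta,gamma Property weights.
#' @param mean_distance Target mean of the 190 pairwise distances.
#' @return An object of class `grantham_model`: properties, weights and the
#'   normalization constant `rho`.
#' @export
grantham_model <- function(alpha = 1.833, beta = 0.1018, gamma = 0.000399,
                           mean_distance = 100) {
  pr <- grantham_properties()
  raw <- raw_grantham(pr, alpha, beta, gamma)
  rho <- mean_distance / mean(raw[lower.tri(raw)])
  structure(list(properties = pr, alpha = alpha, beta = beta, gamma = gamma,
                 rho = rho),
            class = "grantham_model")
}

raw_grantham <- function(pr, alpha, beta, gamma) {
  d2 <- function(x) outer(x, x, "-")^2
  m <- sqrt(alpha * d2(pr$c) + beta * d2(pr$p) + gamma * d2(pr$v))
  dimnames(m) <- list(pr$aa, pr$aa)
  m
}

#' @export
print.grantham_model <- function(x, ...) {
  cat("<grantham_model> alpha=", x$alpha, " beta=", x$beta,
      " gamma=", x$gamma, " rho=", round(x$rho, 4), "\n", sep = "")
  invisible(x)
}

#' Grantham distance between two amino acids
#'
#' @param aa_from,aa_to Standard single-letter residue codes (vectorized).
#' @param model A [grantham_model()].
#' @param rounded Report the conventional integer score (default) or the
#'   full-precision value.
#' @return Numeric vector of distances; 0 iff the residues are identical.
#' @export
grantham_distance <- function(aa_from, aa_to, model = grantham_model(),
                              rounded = TRUE) {
  aa_from <- toupper(aa_from)
  aa_to <- toupper(aa_to)
  bad <- setdiff(unique(c(aa_from, aa_to)), model$properties$aa)
  if (length(bad))
    stop("not a standard amino acid letter: ", paste(bad, collapse = ", "))
  m <- raw_grantham(model$properties, model$alpha, model$beta, model$gamma) *
    model$rho
  d <- m[cbind(aa_from, aa_to)]
  if (rounded) round(d) else d
}

#' Full 20x20 Grantham distance matrix
#'
#' @inheritParams grantham_distance
#' @return Symmetric 20x20 matrix with zero diagonal, residues in Grantham's
#'   row order.
#' @export
grantham_matrix <- function(model = grantham_model(), rounded = TRUE) {
  m <- raw_grantham(model$properties, model$alpha, model$beta, model$gamma) *
    model$rho
  if (rounded) round(m) else m
}

#' Parse a single-letter protein change
#'
#' @param protein Strings like `"D801N"`.
#' @return `data.frame` with `aa_from`, `residue`, `aa_to`; `NA` rows for
#'   unparsable input.
#' @export
parse_protein_change <- function(protein) {
  m <- regmatches(protein,
                  regexec("^([A-Za-z])([0-9]+)([A-Za-z])$",
                          ifelse(is.na(protein), "", protein)))
  data.frame(
    aa_from = vapply(m, function(x) if (length(x) == 4) toupper(x[[2]]) else NA_character_, ""),
    residue = vapply(m, function(x) if (length(x) == 4) as.integer(x[[3]]) else NA_integer_, 1L),
    aa_to = vapply(m, function(x) if (length(x) == 4) toupper(x[[4]]) else NA_character_, ""),
    stringsAsFactors = FALSE)
}
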