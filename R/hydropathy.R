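# Hydropathy scales and sliding-window machinery used by the TM predictor.

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values for the 20 standard amino acids on the
#' Kyte-Doolittle scale. Positive values are hydrophobic; membrane-spanning
#' alpha-helices average well above zero over a ~19-residue window.
#'
#' @return Named numeric vector of length 20 (one-letter residue codes).
#' @export
#' @examples
#' kyte_doolittle()[c("L", "K")]
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Construct a hydropathy scale object
#'
#' @param values named numeric vector mapping each of the 20 standard residues
#'   to a hydropathy score.
#' @param name label for the scale.
#' @return An object of class \code{hydropathy_scale}.
#' @export
hydropathy_scale <- function(values = kyte_doolittle(), name = "kyte_doolittle") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aa %in% names(values)))
    stop("hydropathy scale must cover all 20 standard residues; missing: ",
         paste(setdiff(aa, names(values)), collapse = ", "))
  structure(list(values = values[aa], name = name), class = "hydropathy_scale")
}

#' @export
print.hydropathy_scale <- function(x, ...) {
  cat("Hydropathy scale:", x$name, "\n")
  print(round(x$values, 2))
  invisible(x)
}

# Per-residue hydropathy of a sequence (character string) under a scale.
residue_hydropathy <- function(sequence, scale = hydropathy_scale()) {
  res <- strsplit(sequence, "")[[1]]
  h <- unname(scale$values[res])
  if (anyNA(h))
    stop("sequence contains nonstandard residues: ",
         paste(unique(res[is.na(h)]), collapse = ", "),
         " (sanitize first, see sanitize_sequence)")
  h
}

# Means of all windows of size w; element i is the mean over positions
# [i, i + w - 1]. Returns numeric(0) when the sequence is shorter than w.
window_means <- function(h, w) {
  n <- length(h)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, h))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}
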