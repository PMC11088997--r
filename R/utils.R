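#' Derive a child seed from a root seed
#'
#' One root seed determines the whole simulation; each module draws from its
#' own stream so stages can be re-run independently without perturbing the
#' others. The scheme is a fixed affine congruential step modulo 2^31 - 1:
#' \code{child = (48271 * (seed mod 2^31-1) + 69621 * stream + 1) mod 2^31-1}.
#'
#' @param seed integer root seed.
#' @param stream nonnegative integer stream index.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(stream) * 69621 + 1) %% 2147483647)
}

#' Pairwise Hamming distance matrix for equal-length sequences
#'
#' Computed by one-hot incidence cross-products over the A/C/G/T/N alphabet,
#' so the cost is a handful of dense matrix products rather than an explicit
#' all-pairs character scan.
#'
#' @param x character vector of equal-length strings.
#' @return integer matrix of pairwise Hamming distances.
#' @export
hamming_distance_matrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), 0L, 0L))
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("all sequences must have equal length")
  ints <- matrix(utf8ToInt(paste(x, collapse = "")), nrow = L)
  matches <- matrix(0, n, n)
  for (b in utf8ToInt("ACGTN")) {
    I <- t(ints == b) * 1
    matches <- matches + tcrossprod(I)
  }
  D <- L - matches
  storage.mode(D) <- "integer"
  dimnames(D) <- list(x, x)
  D
}

# Union-find with path halving; `parent` is modified and returned.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Connected components from an edge list over nodes 1..n.
# Returns an integer component label per node (root index).
connected_components <- function(n, from, to) {
  parent <- seq_len(n)
  for (k in seq_along(from)) {
    ri <- uf_find(parent, from[k])
    rj <- uf_find(parent, to[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# Phred string (offset 33) <-> integer vector helpers.
phred_to_int <- function(q) utf8ToInt(q) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)

stop_if_not_prob <- function(p, what) {
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-12)
    stop(sprintf("%s must be probabilities summing to 1", what))
  invisible(p)
}
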