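#' Genotype constructors and serialisation
#'
#' A genotype is a 0/1 integer vector of length N whose i-th entry marks the
#' presence of the i-th internal reaction of a universe (the internal-reaction
#' ordering defines the bit positions).  Genotypes serialise to hex strings;
#' the encoding is invertible given N.
#'
#' @param u a [reaction_universe()].
#' @param ids character vector of internal reaction ids to set present.
#' @return integer 0/1 vector of length \code{universe_N(u)}.
#' @export
genotype_from_ids <- function(u, ids) {
  internal <- u$reaction_ids[u$internal_idx]
  bad <- setdiff(ids, internal)
  if (length(bad))
    stop("not internal reaction(s) of this universe: ",
         paste(bad, collapse = ", "))
  as.integer(internal %in% ids)
}

#' @rdname genotype_from_ids
#' @export
full_genotype <- function(u) rep(1L, universe_N(u))

#' @rdname genotype_from_ids
#' @param g a genotype bit vector.
#' @export
genotype_ids <- function(u, g) u$reaction_ids[u$internal_idx][g == 1L]

#' @rdname genotype_from_ids
#' @export
genotype_size <- function(g) sum(g == 1L)

#' Hex serialisation of genotype bit vectors
#'
#' Bits are packed four at a time, bit 1 first (most significant within its
#' nibble); trailing pad bits are zero.  \code{genotype_from_hex} inverts the
#' encoding given the genotype length.
#'
#' @param g genotype bit vector.
#' @return a hex string.
#' @export
genotype_to_hex <- function(g) {
  n <- length(g)
  pad <- (4 - n %% 4) %% 4
  bits <- c(as.integer(g), rep(0L, pad))
  nib <- vapply(seq_len(length(bits) / 4), function(k) {
    b <- bits[(4 * k - 3):(4 * k)]
    sum(b * c(8L, 4L, 2L, 1L))
  }, integer(1))
  paste(strsplit("0123456789abcdef", "")[[1]][nib + 1L], collapse = "")
}

#' @rdname genotype_to_hex
#' @param hex hex string produced by \code{genotype_to_hex}.
#' @param n genotype length N.
#' @export
genotype_from_hex <- function(hex, n) {
  nibs <- match(strsplit(tolower(hex), "")[[1]],
                strsplit("0123456789abcdef", "")[[1]]) - 1L
  if (anyNA(nibs)) stop("not a hex string: ", hex)
  bits <- unlist(lapply(nibs, function(v)
    as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L)))
  if (length(bits) < n) stop("hex string too short for n = ", n)
  extra <- bits[(n + 1):length(bits)]
  if (n < length(bits) && any(extra == 1L))
    stop("hex string has set bits beyond position ", n)
  bits[seq_len(n)]
}

# --- bitmask representation (N <= 30) --------------------------------------
# Genotype sets are stored as integer masks, bit (i-1) <-> internal reaction i.

bits_to_mask <- function(g) {
  n <- length(g)
  stopifnot(n <= 30L)
  as.integer(sum(as.numeric(g) * 2^(seq_len(n) - 1)))
}

mask_to_bits <- function(mask, n) {
  as.integer(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
}

masks_to_matrix <- function(masks, n) {
  out <- matrix(0L, length(masks), n)
  for (i in seq_len(n))
    out[, i] <- as.integer(bitwAnd(masks, bitwShiftL(1L, i - 1L)) != 0L)
  out
}
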