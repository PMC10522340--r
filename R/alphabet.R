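#' Amino-acid alphabet with gap
#'
#' The categorical state space used at residue sites of aligned sequences:
#' the 20 standard amino acids followed by the gap character \code{"-"},
#' 21 symbols in total. States are 1-based integer indices into this vector;
#' the gap always occupies the last index.
#'
#' @return Character vector of length 21 (20 amino acids then \code{"-"}).
#' @export
#' @examples
#' aminoAlphabet()
aminoAlphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
}

#' @rdname aminoAlphabet
#' @export
gapIndex <- function() 21L

residueCardinality <- function() 21L

#' TRBV/TRBJ gene catalogs
#'
#' Fixed ordered catalogs of 48 functional TRBV and 13 functional TRBJ gene
#' labels, defining the categorical state spaces of the optional V and J
#' sites of encoded TCR records (cardinalities 48 and 13). Shipped as a JSON
#' data file so the ordering is explicit and stable; unknown labels are
#' rejected, never silently binned.
#'
#' @return List with character vectors \code{v} (48 labels) and \code{j}
#'   (13 labels).
#' @export
geneCatalogs <- function() {
  path <- system.file("extdata", "gene_catalogs.json", package = "diffrbm")
  cat <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(length(cat$v) == 48L, length(cat$j) == 13L)
  cat
}

#' Encode residue strings as integer state matrices
#'
#' Converts equal-length residue strings (which may contain gaps) into an
#' integer matrix of 1-based states with a \code{cardinalities} attribute,
#' the aligned-dataset representation used throughout the package. With
#' \code{vGene}/\code{jGene}, two extra categorical sites (cardinalities
#' 48 and 13) are appended after the residue sites.
#'
#' @param seqs Character vector of equal-length residue strings.
#' @param vGene,jGene Optional character vectors of TRBV/TRBJ labels
#'   (both or neither), matched against [geneCatalogs()].
#' @return Integer matrix, one row per sequence, with attribute
#'   \code{cardinalities} (integer vector, one entry per column).
#' @export
#' @examples
#' encodeSequences(c("NLVPMVATV", "GILGFVFTL"))
encodeSequences <- function(seqs, vGene = NULL, jGene = NULL) {
  if (length(seqs) == 0L) stop("no sequences to encode")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must all have the same length; align them first")
  alpha <- aminoAlphabet()
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                  byrow = TRUE)
  states <- matrix(match(chars, alpha), nrow = length(seqs))
  if (anyNA(states)) {
    bad <- which(apply(is.na(states), 1L, any))
    stop("invalid residue characters in sequence(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  card <- rep(residueCardinality(), ncol(states))
  if (!is.null(vGene) || !is.null(jGene)) {
    if (is.null(vGene) || is.null(jGene))
      stop("vGene and jGene must be supplied together")
    cats <- geneCatalogs()
    vi <- match(vGene, cats$v)
    ji <- match(jGene, cats$j)
    if (anyNA(vi))
      stop("unknown V gene label(s): ",
           paste(unique(vGene[is.na(vi)]), collapse = ", "),
           " (see geneCatalogs()$v)")
    if (anyNA(ji))
      stop("unknown J gene label(s): ",
           paste(unique(jGene[is.na(ji)]), collapse = ", "),
           " (see geneCatalogs()$j)")
    states <- cbind(states, vi, ji)
    card <- c(card, length(cats$v), length(cats$j))
  }
  dimnames(states) <- NULL
  attr(states, "cardinalities") <- as.integer(card)
  storage.mode(states) <- "integer"
  states
}

#' @rdname encodeSequences
#' @param states Integer state matrix as produced by [encodeSequences()].
#' @param dropGaps Remove gap characters from the output strings.
#' @export
decodeSequences <- function(states, dropGaps = FALSE) {
  card <- cardinalities(states)
  res <- which(card == residueCardinality())
  alpha <- aminoAlphabet()
  out <- unname(apply(states[, res, drop = FALSE], 1L,
                      function(s) paste(alpha[s], collapse = "")))
  if (dropGaps) out <- gsub("-", "", out, fixed = TRUE)
  out
}

#' Per-site cardinalities of an encoded dataset
#'
#' @param states Integer state matrix with a \code{cardinalities} attribute,
#'   or a model object.
#' @return Integer vector of per-site state-space sizes.
#' @export
cardinalities <- function(states) {
  card <- attr(states, "cardinalities")
  if (is.null(card)) {
    if (is.matrix(states)) {
      # plain matrix of residue states: assume amino-acid sites
      card <- rep(residueCardinality(), ncol(states))
    } else stop("no cardinalities attribute")
  }
  as.integer(card)
}

asStateMatrix <- function(states, card = NULL) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1L)
  card <- card %||% cardinalities(states)
  stopifnot(ncol(states) == length(card))
  if (any(states < 1L) || any(states > rep(card, each = nrow(states))))
    stop("state indices out of range for the given cardinalities")
  attr(states, "cardinalities") <- as.integer(card)
  storage.mode(states) <- "integer"
  states
}

# which sites are residue (amino-acid) sites as opposed to gene sites
residueSites <- function(card) which(card == residueCardinality())

# sparse one-hot encoding: n x sum(cardinalities)
oneHot <- function(states, card = NULL) {
  states <- asStateMatrix(states, card)
  card <- cardinalities(states)
  off <- c(0L, cumsum(card))[seq_along(card)]
  n <- nrow(states)
  jj <- as.vector(t(states) + off)           # column-major over sites
  ii <- rep(seq_len(n), each = length(card))
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n, sum(card)))
}

# flat index of (site, state) pairs into a length-sum(card) vector
flatIndex <- function(site, state, card) {
  off <- c(0L, cumsum(card))
  off[site] + state
}
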