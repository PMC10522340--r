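#' Profile aligner to a fixed model length
#'
#' Maps variable-length sequences onto the fixed model length (9 for
#' peptides, 20 for CDR3\eqn{\beta}) using position-specific symbol
#' log-frequencies learnt from a background seed alignment.
#'
#' Peptides (target length 9, inputs 8-11): 9-mers pass through unchanged;
#' 8-mers receive one gap at the placement maximizing the profile
#' likelihood (all placements enumerated, ties to the leftmost); 10/11-mers
#' are mapped by deleting the 1 or 2 internal positions whose removal
#' maximizes the profile likelihood of the remaining 9-mer (ties leftmost).
#'
#' CDR3\eqn{\beta} (target length 20, inputs 5-25): the first
#' \eqn{\lceil L/2 \rceil} residues are anchored on the left and the rest on
#' the right, with all gaps inserted centrally between the two blocks
#' (sequences longer than 20 lose their most central residues). This
#' anchored rule reflects the conserved ends of CDR3 loops.
#'
#' @slot targetLength Integer, 9 or 20.
#' @slot logProfile Matrix \code{targetLength x 21} of pseudocounted
#'   position-specific symbol log-frequencies (gap included).
#' @slot mode \code{"peptide"} or \code{"cdr3"}.
#' @export
setClass("ProfileAligner",
         representation(targetLength = "integer", logProfile = "matrix",
                        mode = "character"))

setMethod("show", "ProfileAligner", function(object) {
  cat(sprintf("ProfileAligner [%s], target length %d\n", object@mode,
              object@targetLength))
})

supportedLengths <- function(mode) {
  if (mode == "peptide") 8:11 else 5:25
}

profileFromAligned <- function(alignedStates, targetLength) {
  q <- residueCardinality()
  counts <- matrix(1 / q, targetLength, q)   # pseudocount
  for (i in seq_len(targetLength)) {
    tab <- tabulate(alignedStates[, i], nbins = q)
    counts[i, ] <- counts[i, ] + tab
  }
  log(counts / rowSums(counts))
}

#' Build a profile aligner from a background dataset
#'
#' Seed statistics come only from the background set, making alignments of
#' selected datasets consistent with the background model they are scored
#' against. Deterministic given the input (order-independent statistics).
#'
#' @param background Character vector of background residue sequences
#'   (no gaps), or a \code{data.frame} from [readSequences()].
#' @param targetLength 9 (peptides) or 20 (CDR3\eqn{\beta}).
#' @return A [ProfileAligner-class].
#' @export
buildProfileAligner <- function(background, targetLength) {
  if (is.data.frame(background)) background <- background$sequence
  stopifnot(length(background) > 0, targetLength %in% c(9L, 20L))
  mode <- if (targetLength == 9L) "peptide" else "cdr3"
  lens <- nchar(background)
  if (any(!lens %in% supportedLengths(mode)))
    stop("background sequences outside the supported length range (",
         min(supportedLengths(mode)), "-", max(supportedLengths(mode)),
         "): entries ",
         paste(head(which(!lens %in% supportedLengths(mode)), 5L),
               collapse = ", "))
  targetLength <- as.integer(targetLength)
  q <- residueCardinality()
  al <- new("ProfileAligner", targetLength = targetLength,
            logProfile = matrix(log(1 / q), targetLength, q), mode = mode)
  if (mode == "peptide") {
    # seed: exact-length sequences as-is, then one refinement round over all
    exact <- background[lens == targetLength]
    if (length(exact) > 0)
      al@logProfile <- profileFromAligned(encodeSequences(exact),
                                          targetLength)
    aligned <- alignSequences(al, background)
    al@logProfile <- profileFromAligned(aligned, targetLength)
  } else {
    aligned <- alignSequences(al, background)
    al@logProfile <- profileFromAligned(aligned, targetLength)
  }
  al
}

# all candidate 9-mer state vectors for one peptide + profile scores
alignPeptideStates <- function(states, targetLength, logProfile) {
  L <- length(states)
  gap <- gapIndex()
  if (L == targetLength) return(states)
  cands <- if (L < targetLength) {
    # single gap inserted at each possible placement
    lapply(seq_len(targetLength), function(g)
      append(states, gap, after = g - 1L))
  } else {
    # delete internal positions (never the terminal anchors)
    drop <- combn(2:(L - 1L), L - targetLength, simplify = FALSE)
    lapply(drop, function(d) states[-d])
  }
  sc <- vapply(cands, function(s)
    sum(logProfile[cbind(seq_len(targetLength), s)]), numeric(1))
  cands[[which.max(sc)]]                     # ties: leftmost
}

alignCDR3States <- function(states, targetLength) {
  L <- length(states)
  if (L == targetLength) return(states)
  if (L < targetLength) {
    left <- ceiling(L / 2)
    c(states[seq_len(left)], rep(gapIndex(), targetLength - L),
      states[(left + 1L):L])
  } else {
    keepL <- ceiling(targetLength / 2)
    keepR <- targetLength - keepL
    c(states[seq_len(keepL)], states[(L - keepR + 1L):L])
  }
}

#' Align sequences against a profile
#'
#' @param aligner A [ProfileAligner-class].
#' @param seqs Character vector of residue sequences (lengths within the
#'   aligner's supported range), or a \code{data.frame} from
#'   [readSequences()].
#' @param withGenes Append V and J gene sites (cardinalities 48 and 13)
#'   after the residue sites; requires \code{vGene}/\code{jGene} (or the
#'   corresponding \code{data.frame} columns).
#' @param vGene,jGene Gene labels, matched against [geneCatalogs()].
#' @return Integer state matrix with \code{cardinalities} attribute;
#'   removing gap states recovers each input sequence (when no deletion was
#'   forced by an over-long input).
#' @export
alignSequences <- function(aligner, seqs, withGenes = FALSE,
                           vGene = NULL, jGene = NULL) {
  stopifnot(is(aligner, "ProfileAligner"))
  if (is.data.frame(seqs)) {
    vGene <- vGene %||% seqs$v_gene
    jGene <- jGene %||% seqs$j_gene
    seqs <- seqs$sequence
  }
  lens <- nchar(seqs)
  ok <- lens %in% supportedLengths(aligner@mode)
  if (!all(ok))
    stop("sequence length outside supported range: entries ",
         paste(head(which(!ok), 5L), collapse = ", "))
  alpha <- aminoAlphabet()
  tl <- aligner@targetLength
  out <- matrix(0L, length(seqs), tl)
  for (k in seq_along(seqs)) {
    st <- match(strsplit(seqs[k], "")[[1]], alpha)
    if (anyNA(st) || any(st == gapIndex()))
      stop("invalid residue characters in sequence ", k)
    out[k, ] <- if (aligner@mode == "peptide")
      alignPeptideStates(st, tl, aligner@logProfile)
    else alignCDR3States(st, tl)
  }
  card <- rep(residueCardinality(), tl)
  if (withGenes) {
    if (is.null(vGene) || is.null(jGene))
      stop("withGenes = TRUE requires vGene and jGene labels")
    cats <- geneCatalogs()
    vi <- match(vGene, cats$v); ji <- match(jGene, cats$j)
    if (anyNA(vi))
      stop("unknown V gene label(s): ",
           paste(unique(vGene[is.na(vi)]), collapse = ", "),
           " (see geneCatalogs()$v)")
    if (anyNA(ji))
      stop("unknown J gene label(s): ",
           paste(unique(jGene[is.na(ji)]), collapse = ", "))
    out <- cbind(out, vi, ji)
    card <- c(card, length(cats$v), length(cats$j))
  }
  dimnames(out) <- NULL
  attr(out, "cardinalities") <- as.integer(card)
  storage.mode(out) <- "integer"
  out
}

#' Redundancy reweighting by sequence similarity
#'
#' Weighs each aligned sequence by the inverse of the number of sequences
#' in the set (itself included) whose pairwise identity fraction exceeds
#' \code{threshold}. Identity is computed over residue sites only (gene
#' sites excluded); positions where both sequences carry a gap count as
#' matches. A weight of 1 means no other sequence exceeds the threshold.
#'
#' @param states Integer state matrix of aligned sequences.
#' @param threshold Identity fraction above which two sequences count as
#'   similar (default 0.8).
#' @return Numeric vector of weights in \eqn{(0, 1]}.
#' @export
similarityReweight <- function(states, threshold = 0.8) {
  states <- asStateMatrix(states)
  if (nrow(states) == 0L) stop("empty sequence list")
  card <- cardinalities(states)
  res <- residueSites(card)
  sub <- states[, res, drop = FALSE]
  attr(sub, "cardinalities") <- card[res]
  X <- oneHot(sub)
  matches <- as.matrix(Matrix::tcrossprod(X))     # pairwise identical sites
  similar <- matches / length(res) > threshold
  1 / rowSums(similar)
}
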