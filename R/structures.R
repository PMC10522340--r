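#' Parse a TCR-pMHC structure into chains with heavy-atom coordinates
#'
#' Reads a PDB or mmCIF file (via \pkg{bio3d}) and organizes it by chain
#' role. Hydrogen/deuterium atoms are discarded; when alternate
#' conformations are present only the highest-occupancy one per atom is
#' kept. Residues are indexed by sequential 1-based rank along each chain
#' (positions count along the sequence, not author numbering). For a chain
#' with role \code{"tcrb"}, the CDR3\eqn{\beta} span is located between the
#' conserved cysteine and the phenylalanine of the FG.G motif when not
#' supplied in \code{roleMap}.
#'
#' @param path PDB (\code{.pdb}) or mmCIF (\code{.cif}) file.
#' @param roleMap Named list mapping chain identifiers to roles among
#'   \code{"peptide"}, \code{"hla"}, \code{"tcrb"}, \code{"other"}; may
#'   carry an optional \code{cdr3Span} entry \code{c(start, end)} (ranks
#'   along the tcrb chain).
#' @return A \code{structureComplex}: list with \code{id} and per-chain
#'   entries holding \code{role}, \code{sequence}, \code{atoms}
#'   (data.frame: \code{rank}, \code{x}, \code{y}, \code{z}, \code{elem})
#'   and, for tcrb chains, \code{cdr3Span}.
#' @export
parseStructure <- function(path, roleMap) {
  if (!file.exists(path)) stop("file not found: ", path)
  cdr3Span <- roleMap$cdr3Span
  roleMap$cdr3Span <- NULL
  roles <- unlist(roleMap)
  if (!"peptide" %in% roles || length(roles) < 2L)
    stop("roleMap must cover the peptide and at least one partner chain")
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE))
  else suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- toupper(trimws(at$elesy %||% ""))
  if (all(!nzchar(elem)))                     # fall back to atom-name guess
    elem <- toupper(substr(trimws(at$elety), 1L, 1L))
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]

  out <- list(id = sub("\\.(pdb|cif)$", "", basename(path),
                       ignore.case = TRUE),
              chains = list())
  for (ch in names(roleMap)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    if (nrow(sub) == 0L) stop("missing chain in structure: ", ch)
    # highest-occupancy conformer per (residue, atom name)
    key <- paste(sub$resno, sub$insert %||% "", sub$elety)
    occ <- sub$o %||% rep(1, nrow(sub))
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(sub)), key),
                          function(ii) ii[which.max(occ[ii])]))
    sub <- sub[sort(keep), , drop = FALSE]
    rkey <- paste(sub$resno, sub$insert %||% "")
    rank <- match(rkey, unique(rkey))
    res3 <- vapply(split(sub$resid, rank), function(r) r[1L], character(1))
    seq1 <- paste(bio3d::aa321(res3), collapse = "")
    if (grepl("X", seq1, fixed = TRUE))
      stop("unresolvable residue(s) in chain ", ch, ": ",
           paste(unique(res3[bio3d::aa321(res3) == "X"]), collapse = ", "))
    chain <- list(role = roleMap[[ch]], sequence = seq1,
                  atoms = data.frame(rank = rank, x = sub$x, y = sub$y,
                                     z = sub$z))
    if (roleMap[[ch]] == "tcrb")
      chain$cdr3Span <- cdr3Span %||%
        tryCatch(findCDR3Span(seq1), error = function(e) NULL)
    out$chains[[ch]] <- chain
  }
  pep <- vapply(out$chains, function(c) c$role == "peptide", logical(1))
  plen <- nchar(out$chains[[which(pep)[1L]]]$sequence)
  if (plen < 8L || plen > 11L)
    warning("peptide chain length ", plen, " outside the 8-11 range")
  class(out) <- "structureComplex"
  out
}

# CDR3 span along a beta-chain sequence: conserved Cys to the Phe of the
# FG.G motif (both included); falls back to the last C / following F pair.
findCDR3Span <- function(seq1) {
  m <- regexpr("C[A-Z]{3,23}?FG.G", seq1)
  if (m > 0) {
    fpos <- as.integer(m) + attr(m, "match.length") - 4L
    return(c(as.integer(m), fpos))
  }
  cs <- gregexpr("C", seq1)[[1]]
  fs <- gregexpr("F", seq1)[[1]]
  for (cc in rev(cs[cs > 0])) {
    cand <- fs[fs > cc + 3L & fs <= cc + 24L]
    if (length(cand) > 0) return(c(cc, cand[1L]))
  }
  stop("could not locate a CDR3 (C...F) span; supply cdr3Span in roleMap")
}

#' Extract contact positions from a structure
#'
#' A query-chain position is a contact iff any of its heavy atoms lies
#' within \code{cutoff} (boundary-inclusive) of any heavy atom of a partner
#' chain. Default cutoffs follow the standard conventions: 4.0 A for
#' peptide-TCR and CDR3\eqn{\beta}-peptide contacts and 3.5 A for
#' peptide-HLA contacts; larger values can be set for robustness analyses.
#' When the query role is \code{"tcrb"}, positions are reported along the
#' CDR3\eqn{\beta} span (1-based within the span) and the entry sequence is
#' the CDR3\eqn{\beta}.
#'
#' @param cx A \code{structureComplex} from [parseStructure()].
#' @param query Role of the chain whose positions are reported
#'   (\code{"peptide"} or \code{"tcrb"}).
#' @param partner Role of the partner chain(s) (\code{"tcrb"},
#'   \code{"hla"} or \code{"peptide"}).
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return A one-row \code{data.frame} contact entry: \code{structure},
#'   \code{query}, \code{partner}, \code{sequence}, \code{contacts}
#'   (list column of integer positions), \code{cutoff}.
#' @export
computeContacts <- function(cx, query = "peptide", partner = "tcrb",
                            cutoff = 4.0) {
  stopifnot(inherits(cx, "structureComplex"), cutoff > 0)
  pick <- function(role) {
    hit <- Filter(function(c) c$role == role, cx$chains)
    if (length(hit) == 0L) stop("no chain with role: ", role)
    hit
  }
  qc <- pick(query)[[1L]]
  pcs <- pick(partner)
  pxyz <- do.call(rbind, lapply(pcs, function(c)
    as.matrix(c$atoms[, c("x", "y", "z")])))
  if (nrow(pxyz) == 0L) stop("empty partner chain")
  qa <- qc$atoms
  if (identical(query, "tcrb")) {
    span <- qc$cdr3Span
    if (is.null(span))
      stop("no CDR3 (C...F) span could be located on the tcrb chain; ",
           "supply cdr3Span in the roleMap of parseStructure()")
    qa <- qa[qa$rank >= span[1L] & qa$rank <= span[2L], , drop = FALSE]
    qa$rank <- qa$rank - span[1L] + 1L
    seq1 <- substr(qc$sequence, span[1L], span[2L])
  } else seq1 <- qc$sequence
  qxyz <- as.matrix(qa[, c("x", "y", "z")])
  d2 <- outer(rowSums(qxyz^2), rowSums(pxyz^2), `+`) -
    2 * qxyz %*% t(pxyz)
  mind2 <- apply(d2, 1L, min)
  hit <- sort(unique(qa$rank[sqrt(pmax(mind2, 0)) <= cutoff]))
  data.frame(structure = cx$id, query = query, partner = partner,
             sequence = seq1, contacts = I(list(as.integer(hit))),
             cutoff = cutoff)
}

#' Deduplicate contact entries
#'
#' Keeps one entry per unique (sequence, contact set) combination; the same
#' sequence annotated with different contact sets stays as separate
#' entries. Idempotent.
#'
#' @param entries \code{data.frame} of contact entries (rows as returned by
#'   [computeContacts()], possibly concatenated).
#' @return The deduplicated \code{data.frame}.
#' @export
deduplicateEntries <- function(entries) {
  if (NROW(entries) == 0L) return(entries)
  key <- paste(entries$sequence,
               vapply(entries$contacts, function(cc)
                 paste(sort(cc), collapse = ","), character(1)))
  entries[!duplicated(key), , drop = FALSE]
}

#' Entry multiplicities and effective count
#'
#' Sets \eqn{n_\sigma} for each (deduplicated) entry to the number of
#' entries, itself included, whose sequence is equal to or one substitution
#' away from its own (Hamming distance at most 1 over equal-length
#' sequences; sequences of different lengths are always farther than 1),
#' and computes \eqn{R_{eff} = \sum_r 1/n_{\sigma_r} \le R} (equality iff
#' all sequences are pairwise at distance 2 or more).
#'
#' @param entries \code{data.frame} of deduplicated contact entries.
#' @return The \code{data.frame} with an \code{n_sigma} column, plus
#'   attribute \code{"Reff"}.
#' @export
contactMultiplicities <- function(entries) {
  seqs <- entries$sequence
  n <- length(seqs)
  lens <- nchar(seqs)
  ns <- integer(n)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(n)) {
    ns[i] <- sum(vapply(seq_len(n), function(j) {
      if (lens[i] != lens[j]) return(FALSE)
      sum(chars[[i]] != chars[[j]]) <= 1L
    }, logical(1)))
  }
  entries$n_sigma <- ns
  attr(entries, "Reff") <- sum(1 / ns)
  entries
}

#' Convert CDR3 positions to anchor-relative coordinates
#'
#' CDR3\eqn{\beta} positions are conventionally reported as distances to
#' the nearest anchor: position \eqn{i} of a length-\eqn{L} loop is
#' \eqn{i - 1} from the left anchor and \eqn{L - i} from the right anchor.
#' The two functions are inverses of each other.
#'
#' @param positions Integer vector of 1-based positions.
#' @param length CDR3 length L.
#' @param from \code{"left"} or \code{"right"}.
#' @return Integer vector of anchor distances (or positions for the
#'   inverse).
#' @export
cdr3AnchorDistance <- function(positions, length, from = c("left", "right")) {
  from <- match.arg(from)
  if (from == "left") positions - 1L else length - positions
}

#' @rdname cdr3AnchorDistance
#' @param distances Integer vector of anchor distances.
#' @export
cdr3PositionFromAnchor <- function(distances, length,
                                   from = c("left", "right")) {
  from <- match.arg(from)
  if (from == "left") distances + 1L else length - distances
}
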