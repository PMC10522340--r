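#' Read sequence records from FASTA, plain-text or tabular files
#'
#' Returns one record per entry as a \code{data.frame} with columns
#' \code{sequence} and (when available) \code{v_gene}, \code{j_gene},
#' \code{hla}, \code{organism}, \code{label}. No deduplication is performed
#' (duplicate lines yield duplicate records). Residues outside the 20
#' amino acids are rejected with the offending entry index.
#'
#' @param path File path.
#' @param format One of \code{"fasta"}, \code{"plain"} (one sequence per
#'   line), \code{"table"} (TSV/CSV with header).
#' @param columns For \code{format = "table"}: named list mapping record
#'   fields to column names, e.g. \code{list(sequence = "cdr3",
#'   v_gene = "v.segm", j_gene = "j.segm")}. Defaults match VDJdb
#'   \code{vdjdb.txt} headers; only \code{sequence} is mandatory.
#' @param sep Field separator for tables (default tab; use \code{","} for
#'   CSV).
#' @return \code{data.frame} of sequence records.
#' @export
readSequences <- function(path, format = c("fasta", "plain", "table"),
                          columns = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- switch(format,
    fasta = {
      ss <- Biostrings::readAAStringSet(path)
      if (length(ss) == 0L) stop("empty FASTA file: ", path)
      data.frame(sequence = as.character(ss), row.names = NULL)
    },
    plain = {
      ln <- readLines(path)
      ln <- ln[nzchar(trimws(ln))]
      if (length(ln) == 0L) stop("empty file: ", path)
      data.frame(sequence = trimws(ln))
    },
    table = {
      columns <- columns %||% list(sequence = "cdr3", v_gene = "v.segm",
                                   j_gene = "j.segm")
      tab <- read.delim(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
      if (nrow(tab) == 0L) stop("empty table: ", path)
      if (is.null(columns$sequence) || !columns$sequence %in% names(tab))
        stop("missing required column: ", columns$sequence %||% "sequence")
      out <- data.frame(sequence = tab[[columns$sequence]])
      for (fld in c("v_gene", "j_gene", "hla", "organism", "label")) {
        cn <- columns[[fld]]
        if (!is.null(cn)) {
          if (!cn %in% names(tab)) stop("missing required column: ", cn)
          out[[fld]] <- tab[[cn]]
        }
      }
      out
    })
  bad <- grepl(sprintf("[^%s]", paste(head(aminoAlphabet(), 20L),
                                      collapse = "")), recs$sequence) |
    !nzchar(recs$sequence)
  if (any(bad))
    stop("malformed residue characters in entry/row: ",
         paste(head(which(bad), 5L), collapse = ", "))
  if (!is.null(recs$v_gene) && is.null(recs$j_gene))
    stop("records with V genes must also carry J genes")
  recs
}

#' Filter an IEDB-style T-cell assay table into peptide records
#'
#' Reproduces the curation used for immunogenicity datasets. After
#' restricting to rows with the requested HLA, linear peptides of length
#' 8-11, antigen-epitope relation \code{"Epitope"} and no
#' \code{"Restimulation in vitro"} step, peptides are classified by their
#' full set of qualitative measures across remaining rows:
#' \describe{
#'   \item{immunogenic}{at least one \code{Positive} or
#'     \code{Positive-High} measure and never a \code{Negative} one;}
#'   \item{non_immunogenic}{at least one \code{Negative} measure and never
#'     any \code{Positive}, \code{Positive-High}, \code{Positive-Intermediate}
#'     or \code{Positive-Low} one.}
#' }
#' Duplicate peptides collapse to a single record. The two modes are
#' disjoint on any table.
#'
#' @param rows \code{data.frame} of assay rows.
#' @param hla HLA restriction to keep (exact match), e.g.
#'   \code{"HLA-A*02:01"}.
#' @param mode \code{"immunogenic"} or \code{"non_immunogenic"}.
#' @param columns Named list mapping the required fields (\code{peptide},
#'   \code{hla}, \code{measure}, \code{relation}, \code{process}) to column
#'   names; defaults match the IEDB \code{tcell_full_v3} export.
#' @return \code{data.frame} with columns \code{sequence}, \code{hla} and,
#'   if an organism column is mapped, \code{organism}.
#' @export
filterImmunogenicityTable <- function(rows, hla,
                                      mode = c("immunogenic",
                                               "non_immunogenic"),
                                      columns = NULL) {
  mode <- match.arg(mode)
  columns <- modifyList(list(peptide = "Description",
                             hla = "Allele Name",
                             measure = "Qualitative Measure",
                             relation = "Antigen Epitope Relation",
                             process = "In Vitro Process Type",
                             organism = NULL),
                        columns %||% list())
  for (fld in c("peptide", "hla", "measure", "relation", "process"))
    if (!columns[[fld]] %in% names(rows))
      stop("missing required column: ", columns[[fld]])

  pep <- as.character(rows[[columns$peptide]])
  keep <- rows[[columns$hla]] == hla &
    nchar(pep) >= 8L & nchar(pep) <= 11L &
    !grepl(sprintf("[^%s]", paste(head(aminoAlphabet(), 20L),
                                  collapse = "")), pep) &
    rows[[columns$relation]] == "Epitope" &
    !grepl("Restimulation in vitro", rows[[columns$process]] %||% "",
           fixed = TRUE)
  keep[is.na(keep)] <- FALSE
  rows <- rows[keep, , drop = FALSE]
  pep <- pep[keep]
  if (nrow(rows) == 0L)
    return(data.frame(sequence = character(0), hla = character(0)))

  posAny <- c("Positive", "Positive-High", "Positive-Intermediate",
              "Positive-Low")
  meas <- split(as.character(rows[[columns$measure]]), pep)
  sel <- vapply(meas, function(m) {
    if (mode == "immunogenic")
      any(m %in% c("Positive", "Positive-High")) && !any(m == "Negative")
    else
      any(m == "Negative") && !any(m %in% posAny)
  }, logical(1))
  peps <- names(meas)[sel]
  out <- data.frame(sequence = peps, hla = hla)
  if (!is.null(columns$organism) && columns$organism %in% names(rows)) {
    org <- vapply(split(as.character(rows[[columns$organism]]), pep),
                  function(o) o[1L], character(1))
    out$organism <- unname(org[peps])
  }
  out
}
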