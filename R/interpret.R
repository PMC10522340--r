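#' Single-site factors
#'
#' Per-position, context-dependent contribution of the realized residue to
#' the differential (or background) part of the model:
#' \deqn{T_i(\sigma_i) = g_i(\sigma_i) +
#'   \sum_{\mu} w_{i\mu}(\sigma_i)\, \langle h_\mu | \sigma \rangle,}
#' where \eqn{\langle h_\mu | \sigma \rangle} is the conditional mean
#' hidden-unit activity at \eqn{I_\mu(\sigma)}. With differential
#' parameters these approximate the log odds-ratio between the full and
#' background model probabilities of residue \eqn{\sigma_i} conditional on
#' the rest of the sequence, and are used to rank putative contact
#' positions; with background parameters they flag the anchor positions of
#' HLA presentation. Factors are reported at residue sites only (gene sites
#' excluded); a model with an all-zero differential part yields all-zero
#' factors.
#'
#' @param model A [DiffRBM-class] (or an [RBM-class], treated as the
#'   background with \code{source = "background"}).
#' @param states Integer state matrix.
#' @param source \code{"diff"} or \code{"background"}.
#' @return Numeric matrix, one row per sequence, one column per residue
#'   site.
#' @export
singleSiteFactors <- function(model, states,
                              source = c("diff", "background")) {
  source <- match.arg(source)
  part <- if (is(model, "RBM")) {
    if (source == "diff") stop("a plain RBM has no differential part")
    model
  } else if (source == "diff") model@diff else model@background
  states <- asStateMatrix(states, part@cardinalities)
  card <- part@cardinalities
  res <- residueSites(card)
  if (length(res) == 0L) res <- seq_along(card)  # toy state spaces
  n <- nrow(states)
  off <- c(0L, cumsum(card))[seq_along(card)]
  flat <- t(t(states) + off)                 # n x N flat (site,state) indices
  gReal <- matrix(part@fields[flat], n, length(card))
  if (nHidden(part) > 0) {
    I <- as.matrix(oneHot(states) %*% part@weights)
    for (mu in seq_len(nHidden(part))) {
      hm <- hiddenMean(part@potentials[[mu]], I[, mu])
      wmat <- matrix(part@weights[, mu][flat], n, length(card))
      gReal <- gReal + wmat * hm
    }
  }
  gReal[, res, drop = FALSE]
}

#' Frequency-ratio single-site factors
#'
#' Baseline factors \eqn{T_i = \log f^{target}_i(\sigma_i) -
#' \log f^{ref}_i(\sigma_i)} from position-specific amino-acid frequencies
#' of a target set (e.g. immunogenic peptides) relative to a reference set
#' (all presented, or non-immunogenic, peptides).
#'
#' @param targetFreqs,refFreqs Position x state frequency matrices
#'   (rows sum to 1, strictly positive after pseudocounting; see
#'   [positionFrequencies()]).
#' @param states Integer state matrix of sequences to evaluate.
#' @return Numeric matrix of factors (one column per residue site).
#' @export
freqRatioFactors <- function(targetFreqs, refFreqs, states) {
  states <- asStateMatrix(states)
  card <- cardinalities(states)
  res <- frequencySites(card)
  stopifnot(nrow(targetFreqs) == length(res), nrow(refFreqs) == length(res))
  if (any(targetFreqs <= 0) || any(refFreqs <= 0))
    stop("frequencies must be strictly positive; apply a pseudocount")
  lr <- log(targetFreqs) - log(refFreqs)
  out <- matrix(0, nrow(states), length(res))
  for (k in seq_along(res))
    out[, k] <- lr[cbind(k, states[, res[k]])]
  out
}

#' Position-specific residue frequencies with pseudocount
#'
#' @param states Integer state matrix.
#' @param pseudocount Added per state, default \code{1/nrow(states)}
#'   (avoids infinite log-ratios on small selected sets).
#' @return Matrix of per-position frequencies over the 21 residue states
#'   (rows sum to 1); residue sites only.
#' @export
positionFrequencies <- function(states, pseudocount = NULL) {
  states <- asStateMatrix(states)
  card <- cardinalities(states)
  res <- frequencySites(card)
  pc <- pseudocount %||% (1 / nrow(states))
  q <- card[res[1L]]
  f <- matrix(0, length(res), q)
  for (k in seq_along(res))
    f[k, ] <- tabulate(states[, res[k]], nbins = q) + pc
  f / rowSums(f)
}

# residue sites when present; otherwise all (equal-cardinality) sites, so
# the frequency machinery also works on toy state spaces
frequencySites <- function(card) {
  res <- residueSites(card)
  if (length(res) > 0) return(res)
  if (length(unique(card)) != 1L)
    stop("mixed cardinalities without residue sites")
  seq_along(card)
}

#' Rank positions by single-site factor magnitude
#'
#' Positions sorted by decreasing \eqn{|T_i|}; gap positions are excluded
#' from the ranking; ties break by ascending position index.
#'
#' @param Tfac Numeric vector of single-site factors for one sequence.
#' @param states Optional state vector of the same sequence, used to
#'   exclude gap positions.
#' @return Integer vector of ranked residue positions.
#' @export
rankPositions <- function(Tfac, states = NULL) {
  pos <- seq_along(Tfac)
  if (!is.null(states)) {
    st <- as.integer(states)[seq_along(Tfac)]
    pos <- pos[st != gapIndex()]
  }
  pos[order(-abs(Tfac[pos]), pos)]
}

#' Positive predictive value curve of a position ranking
#'
#' \eqn{PPV_p} = (true contacts among the top \eqn{p} ranked positions)
#' divided by \eqn{\min(p, |contacts|)}; reaches 1 at \eqn{p} equal to the
#' sequence length.
#'
#' @param ranking Integer vector of ranked positions ([rankPositions()]).
#' @param contacts Integer vector of true contact positions (non-empty).
#' @param length Sequence length (number of p values returned).
#' @return Numeric vector \code{PPV[1..length]}.
#' @export
ppvCurve <- function(ranking, contacts, length) {
  if (base::length(contacts) == 0L) stop("empty contact set")
  vapply(seq_len(length), function(p) {
    top <- ranking[seq_len(min(p, base::length(ranking)))]
    sum(top %in% contacts) / min(p, base::length(contacts))
  }, numeric(1))
}

#' Redundancy-reweighted average PPV
#'
#' Averages per-entry PPV curves with weights \eqn{1/n_\sigma} (entry
#' multiplicities from [contactMultiplicities()]):
#' \eqn{PPV_p = \frac{1}{R_{eff}} \sum_{r=1}^R \frac{1}{n_{\sigma_r}}
#' PPV_{\sigma_r p}}, \eqn{R_{eff} = \sum_r 1/n_{\sigma_r}}. The unweighted
#' mean is returned alongside for comparison.
#'
#' @param curves Numeric matrix of per-entry PPV curves (one row per entry).
#' @param nSigma Integer vector of multiplicities (default all 1, in which
#'   case the weighted and unweighted means coincide and
#'   \eqn{R_{eff} = R}).
#' @return List with \code{ppv} (reweighted curve), \code{unweighted},
#'   \code{Reff}, \code{R}.
#' @export
averagePPV <- function(curves, nSigma = NULL) {
  curves <- rbind(curves)
  R <- nrow(curves)
  nSigma <- nSigma %||% rep(1L, R)
  stopifnot(length(nSigma) == R, all(nSigma >= 1))
  wr <- 1 / nSigma
  Reff <- sum(wr)
  list(ppv = colSums(curves * wr) / Reff,
       unweighted = colMeans(curves),
       Reff = Reff, R = R)
}

#' Analytic random-ranking PPV baseline
#'
#' Expected PPV curve under uniformly random position rankings: the number
#' of contacts among \eqn{p} random positions is hypergeometric with mean
#' \eqn{p\,C/L}, so \eqn{E[PPV_p] = (p\,C/L)/\min(p, C)} for an entry with
#' \eqn{C} contacts over length \eqn{L}. Entries are averaged with the same
#' \eqn{1/n_\sigma} reweighting as [averagePPV()].
#'
#' @param contactCounts Integer vector of contact-set sizes per entry.
#' @param length Sequence length.
#' @param nSigma Optional multiplicities.
#' @return Numeric vector, expected \code{PPV[1..length]}.
#' @export
randomPPVBaseline <- function(contactCounts, length, nSigma = NULL) {
  curves <- t(vapply(contactCounts, function(C)
    vapply(seq_len(length), function(p) (p * C / length) / min(p, C),
           numeric(1)), numeric(length)))
  averagePPV(curves, nSigma)$ppv
}

#' Binomial test for top-ranked contact prediction
#'
#' One-sided upper-tail test of the null hypothesis that top-ranked-position
#' successes occur with probability \code{s}, the average fraction of
#' contact positions per sequence: \eqn{P(X \ge k)}, \eqn{X \sim
#' Binom(n, s)}. The observed count is included in the tail.
#'
#' @param k Observed successes (contacts correctly predicted at rank 1).
#' @param n Number of trials (sequences tested).
#' @param s Null success probability in (0, 1).
#' @return The p-value.
#' @export
binomialContactTest <- function(k, n, s) {
  stopifnot(k >= 0, k <= n, s > 0, s < 1)
  pbinom(k - 1, size = n, prob = s, lower.tail = FALSE)
}
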