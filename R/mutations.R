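#' Experimental mutation cost from EC50 values
#'
#' \eqn{\log(EC50^{MT} / EC50^{WT})} (natural log by default; the base only
#' rescales, and rank-based analyses are base-invariant). Lethal mutations
#' (no recoverable TCR response, formally infinite \eqn{EC50^{MT}}) are
#' handled by the lethal pathway and are an error here.
#'
#' @param ec50Wt,ec50Mt Positive EC50 concentrations (same units, e.g.
#'   ug/ml); invariant under common rescaling.
#' @param base Logarithm base (default \code{exp(1)}).
#' @return Numeric vector of experimental costs.
#' @export
experimentalCost <- function(ec50Wt, ec50Mt, base = exp(1)) {
  if (any(!is.finite(ec50Mt)))
    stop("lethal record (infinite EC50): use the lethal pathway")
  stopifnot(all(ec50Wt > 0), all(ec50Mt > 0))
  log(ec50Mt / ec50Wt, base = base)
}

#' Model-predicted mutation cost
#'
#' \eqn{T_i(\sigma_i) - T_i(\sigma_i')}: the single-site factor of the
#' wild-type residue at position \eqn{i} in the wild-type context, minus
#' the factor of the mutant residue with only site \eqn{i} changed.
#' Differential factors (\code{source = "diff"}) quantify the predicted
#' loss of immunogenicity (used for lethal-mutation analyses); background
#' factors (\code{source = "background"}) quantify the predicted loss of
#' presentation. Exactly antisymmetric under swapping wild type and mutant.
#'
#' @param model A [DiffRBM-class].
#' @param wtStates Integer state vector (or 1-row matrix) of the aligned
#'   wild-type sequence.
#' @param position Residue position i (1-based along the residue sites).
#' @param mtSymbol Mutant amino-acid character.
#' @param source \code{"diff"} or \code{"background"}.
#' @return Numeric predicted cost (0 with a warning if the mutant equals
#'   the wild type).
#' @export
predictedCost <- function(model, wtStates, position, mtSymbol,
                          source = c("diff", "background")) {
  source <- match.arg(source)
  wt <- asStateMatrix(wtStates,
                      if (is(model, "RBM")) model@cardinalities
                      else model@background@cardinalities)
  stopifnot(nrow(wt) == 1L)
  card <- cardinalities(wt)
  res <- residueSites(card)
  stopifnot(position >= 1L, position <= length(res))
  mtState <- match(mtSymbol, aminoAlphabet())
  if (is.na(mtState)) stop("mutant symbol not in the alphabet: ", mtSymbol)
  site <- res[position]
  if (wt[1L, site] == mtState) {
    warning("mutant equals wild type; cost is 0")
    return(0)
  }
  mt <- wt
  mt[1L, site] <- mtState
  Twt <- singleSiteFactors(model, wt, source)[1L, position]
  Tmt <- singleSiteFactors(model, mt, source)[1L, position]
  Twt - Tmt
}

#' Sign summary of predicted lethal-mutation costs
#'
#' @param costs Numeric vector of predicted costs for lethal records.
#' @param positions Optional integer vector of mutated positions (for the
#'   per-position lethal count histogram).
#' @param nPositions Number of positions for the histogram (default 9).
#' @return List with \code{fractionPositive} (strictly positive costs) and
#'   \code{countsByPosition}.
#' @export
lethalSignSummary <- function(costs, positions = NULL, nPositions = 9L) {
  stopifnot(length(costs) > 0)
  counts <- if (is.null(positions)) NULL
            else tabulate(positions, nbins = nPositions)
  list(fractionPositive = mean(costs > 0), countsByPosition = counts)
}

#' Spearman correlation between experimental and predicted costs
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' computed by exact permutation for \eqn{n \le 9} and by the
#' t-approximation otherwise. Invariant under strictly monotone transforms
#' of either vector.
#'
#' @param experimental,predicted Equal-length numeric vectors
#'   (\eqn{n \ge 3}; non-lethal records only).
#' @return List with \code{rho} and \code{p.value}.
#' @export
correlateCosts <- function(experimental, predicted) {
  n <- length(experimental)
  stopifnot(length(predicted) == n, n >= 3L)
  if (sd(experimental) == 0 || sd(predicted) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(experimental); ry <- rank(predicted)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    # exact permutation null: correlation of every reordering of rx with ry
    perms <- permuteIndices(n)
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rhoPerm <- (matrix(cx[perms], nrow(perms)) %*% cy)[, 1L] / denom
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p.value = p)
}

# all permutations of 1..n as rows (n! x n); n is at most 9
permuteIndices <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permuteIndices(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Control distribution of predicted mutation costs
#'
#' Draws background-presented peptides at random, scores every possible
#' amino-acid substitution at every position (9 x 19 = 171 costs per
#' 9-mer peptide) with differential single-site factors, and compares a
#' set of observed (e.g. lethal) costs against this control by a one-sided
#' Mann-Whitney U test (alternative: observed greater).
#'
#' @param model A [DiffRBM-class].
#' @param backgroundStates Integer state matrix of aligned background
#'   peptides to draw from.
#' @param nSample Number of peptides to draw (with replacement, with a
#'   warning, if more than available).
#' @param seed Integer seed for the draw.
#' @param observed Optional numeric vector of observed costs to test
#'   against the control.
#' @param source Factor source for the costs (default \code{"diff"}).
#' @return List with \code{control} (numeric vector of control costs),
#'   \code{p.value} (one-sided Mann-Whitney, or NULL without
#'   \code{observed}).
#' @export
controlCostDistribution <- function(model, backgroundStates, nSample = 3000L,
                                    seed = 1L, observed = NULL,
                                    source = "diff") {
  states <- asStateMatrix(backgroundStates)
  card <- cardinalities(states)
  res <- residueSites(card)
  n <- nrow(states)
  set.seed(seed)
  if (nSample > n) {
    warning("nSample exceeds available peptides; sampling with replacement")
    idx <- sample.int(n, nSample, replace = TRUE)
  } else idx <- sample.int(n, nSample)
  alpha <- aminoAlphabet()
  part <- if (source == "diff") model@diff else model@background
  costs <- numeric(0)
  # vectorized: factors of the realized sequence, then for each position and
  # substitute state, the factor of the mutated sequence at that position
  for (i in seq_along(res)) {
    sub <- states[idx, , drop = FALSE]
    attr(sub, "cardinalities") <- card
    Twt <- singleSiteFactors(model, sub, source)[, i]
    wtState <- sub[, res[i]]
    for (a in seq_len(20L)) {
      rows <- which(wtState != a & wtState != gapIndex())
      if (length(rows) == 0L) next
      mut <- sub[rows, , drop = FALSE]
      mut[, res[i]] <- a
      attr(mut, "cardinalities") <- card
      Tmt <- singleSiteFactors(model, mut, source)[, i]
      costs <- c(costs, Twt[rows] - Tmt)
    }
  }
  p <- if (!is.null(observed))
    wilcox.test(observed, costs, alternative = "greater",
                exact = FALSE)$p.value
  else NULL
  list(control = costs, p.value = p)
}
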