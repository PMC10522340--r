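#' Repeated random train/test split plans
#'
#' Uniformly random partitions of \code{nItems} items into train and test
#' sets, independent across repeats and reproducible from the seed. The
#' train size is \code{floor(trainFraction * nItems)}; the remainder goes
#' to the test set.
#'
#' @param nItems Number of items (at least 5).
#' @param nRepeats Number of repeats (default 50).
#' @param trainFraction Fraction of items trained on (default 0.8).
#' @param seed Integer seed.
#' @return List of class \code{"splitPlan"}: per-repeat lists with integer
#'   index vectors \code{train} and \code{test}.
#' @export
makeSplits <- function(nItems, nRepeats = 50L, trainFraction = 0.8,
                       seed = 1L) {
  stopifnot(nItems >= 5L)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  nTrain <- floor(trainFraction * nItems)
  set.seed(seed)
  plan <- lapply(seq_len(nRepeats), function(r) {
    tr <- sort(sample.int(nItems, nTrain))
    list(train = tr, test = setdiff(seq_len(nItems), tr))
  })
  structure(plan, class = "splitPlan", nItems = nItems, seed = seed)
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted 1/2 — the Mann-Whitney formulation, exactly the ROC area.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param posScores,negScores Non-empty numeric score vectors.
#' @return AUC in \eqn{[0, 1]}.
#' @export
aucScore <- function(posScores, negScores) {
  np <- length(posScores); nn <- length(negScores)
  if (np == 0L || nn == 0L) stop("empty score vector")
  r <- rank(c(posScores, negScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision
#'
#' \eqn{AP = \sum_k (rec_k - rec_{k-1})\, prec_k} over the score-sorted
#' list (descending), with tied scores grouped into blocks (precision
#' evaluated at each block end).
#'
#' @inheritParams aucScore
#' @return AP in \eqn{[0, 1]}.
#' @export
averagePrecision <- function(posScores, negScores) {
  np <- length(posScores); nn <- length(negScores)
  if (np == 0L || nn == 0L) stop("empty score vector")
  sc <- c(posScores, negScores)
  lab <- c(rep(1L, np), rep(0L, nn))
  lev <- sort(unique(sc), decreasing = TRUE)
  tp <- 0; seen <- 0; ap <- 0
  for (s in lev) {
    inBlock <- sc == s
    tp <- tp + sum(lab[inBlock])
    seen <- seen + sum(inBlock)
    recGain <- sum(lab[inBlock]) / np
    ap <- ap + recGain * (tp / seen)
  }
  ap
}

#' Repeated-split discrimination benchmark
#'
#' For each repeat of the plan: fit the model on the training portion of
#' the positives (and, for the difference score, of the negatives), score
#' the held-out positives and negatives, and record AUC and average
#' precision. When \code{negativePool} is given (TCR-style tasks),
#' negatives are drawn per repeat from the pool with the same size as the
#' positive test set, from an RNG stream separate from the split RNG.
#'
#' @param trainer Function \code{(states, seed) -> model} returning a
#'   [DiffRBM-class] (deterministic given the seed).
#' @param positives,negatives Integer state matrices. \code{negatives} is
#'   split by the plan's test fractions unless \code{negativePool} is used.
#' @param plan A [makeSplits()] plan for the positives.
#' @param scorer One of \code{"diff"}, \code{"full"}, \code{"bg"},
#'   \code{"difference"}.
#' @param negativePool Optional state matrix to draw test negatives from.
#' @param seed Master seed for trainer calls and negative draws.
#' @return List of class \code{"evalReport"}: per-repeat \code{auc} and
#'   \code{ap}, with \code{meanAUC}, \code{sdAUC}, \code{meanAP},
#'   \code{sdAP}.
#' @export
evaluateDiscrimination <- function(trainer, positives, negatives = NULL,
                                   plan, scorer = c("diff", "full", "bg",
                                                    "difference"),
                                   negativePool = NULL, seed = 1L) {
  scorer <- match.arg(scorer)
  positives <- asStateMatrix(positives)
  if (scorer == "difference" && is.null(negatives))
    stop("scorer = \"difference\" requires negatives to train on")
  if (!is.null(negatives)) negatives <- asStateMatrix(negatives)
  if (!is.null(negativePool)) negativePool <- asStateMatrix(negativePool)
  card <- cardinalities(positives)
  negPlan <- if (!is.null(negatives))
    makeSplits(nrow(negatives), length(plan), seed = deriveSeed(seed, 777L))
  auc <- ap <- numeric(length(plan))
  for (r in seq_along(plan)) {
    sp <- plan[[r]]
    trainPos <- positives[sp$train, , drop = FALSE]
    attr(trainPos, "cardinalities") <- card
    model <- trainer(trainPos, deriveSeed(seed, r))
    testPos <- positives[sp$test, , drop = FALSE]
    attr(testPos, "cardinalities") <- card
    if (!is.null(negativePool)) {
      set.seed(deriveSeed(seed, 10000L + r))   # separate negative-draw stream
      idx <- sample.int(nrow(negativePool), min(nrow(testPos),
                                                nrow(negativePool)))
      testNeg <- negativePool[idx, , drop = FALSE]
    } else {
      sn <- negPlan[[r]]
      testNeg <- negatives[sn$test, , drop = FALSE]
    }
    attr(testNeg, "cardinalities") <- card
    scoreWith <- function(m, st) switch(scorer,
      diff = scoreSequences(m, st)$diff,
      full = scoreSequences(m, st)$full,
      bg = scoreSequences(m, st)$background)
    if (scorer == "difference") {
      sn <- negPlan[[r]]
      trainNeg <- negatives[sn$train, , drop = FALSE]
      attr(trainNeg, "cardinalities") <- card
      modelNeg <- trainer(trainNeg, deriveSeed(seed, 20000L + r))
      sp1 <- differenceScore(model, modelNeg, testPos)
      sn1 <- differenceScore(model, modelNeg, testNeg)
    } else {
      sp1 <- scoreWith(model, testPos)
      sn1 <- scoreWith(model, testNeg)
    }
    auc[r] <- aucScore(sp1, sn1)
    ap[r] <- averagePrecision(sp1, sn1)
  }
  structure(list(auc = auc, ap = ap,
                 meanAUC = mean(auc), sdAUC = sd(auc),
                 meanAP = mean(ap), sdAP = sd(ap)),
            class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("evalReport over %d repeats: AUC %.3f +/- %.3f, AP %.3f +/- %.3f\n",
              length(x$auc), x$meanAUC, x$sdAUC, x$meanAP, x$sdAP))
  invisible(x)
}

#' Leave-one-organism-out folds
#'
#' One fold per organism with at least \code{minCount} immunogenic and
#' \code{minCount} non-immunogenic records; the training set excludes all
#' records of the held-out organism.
#'
#' @param records \code{data.frame} with columns \code{organism} and
#'   \code{label} (values \code{"immunogenic"} / \code{"non_immunogenic"}).
#' @param minCount Minimum records per class per held-out organism
#'   (default 15).
#' @return List of folds, each with \code{organism}, \code{train} and
#'   \code{test} row indices; empty (with a warning) if no organism
#'   qualifies.
#' @export
leaveOneOrganismOut <- function(records, minCount = 15L) {
  stopifnot(all(c("organism", "label") %in% names(records)))
  orgs <- unique(records$organism)
  ok <- orgs[vapply(orgs, function(org) {
    sum(records$organism == org & records$label == "immunogenic") >=
      minCount &&
      sum(records$organism == org & records$label == "non_immunogenic") >=
        minCount
  }, logical(1))]
  if (length(ok) == 0L) {
    warning("no organism with at least ", minCount,
            " records in both classes")
    return(list())
  }
  lapply(ok, function(org) {
    test <- which(records$organism == org)
    list(organism = org, train = setdiff(seq_len(nrow(records)), test),
         test = test)
  })
}
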