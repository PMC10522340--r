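#' @include rbm.R
NULL

#' Differential (transfer-learning) RBM
#'
#' A two-part model for selected sequences: a frozen background RBM
#' (trained on the large baseline dataset) plus a differential part with its
#' own fields \eqn{g^d}, weights \eqn{w^d} and hidden-unit potentials,
#' trained on the small selected dataset while the background stays fixed.
#' The combined energy is \eqn{H(\sigma) = H^b(\sigma) + H^d(\sigma)}, so the
#' full-model log-probability score decomposes exactly into a background
#' score and a differential-units score (see [scoreSequences()]).
#' \code{Md = 0} with nonzero differential fields is the "linear" variant
#' in which the differential part carries only single-site fields.
#'
#' @slot background Frozen [RBM-class]; never modified by differential
#'   training.
#' @slot diff [RBM-class] holding the differential parameters (same site
#'   cardinalities as the background).
#' @export
setClass("DiffRBM", representation(background = "RBM", diff = "RBM"))

setValidity("DiffRBM", function(object) {
  if (!identical(object@background@cardinalities, object@diff@cardinalities))
    return("background and differential parts have different cardinalities")
  TRUE
})

setMethod("show", "DiffRBM", function(object) {
  cat(sprintf(
    "DiffRBM: %d sites, background M = %d, differential M = %d\n",
    nSites(object@background), nHidden(object@background),
    nHidden(object@diff)))
})

#' @rdname DiffRBM-class
#' @param background Frozen [RBM-class].
#' @param diff Differential [RBM-class] (default: empty, all parameters 0).
#' @export
diffRBM <- function(background, diff = NULL) {
  new("DiffRBM", background = background,
      diff = diff %||% rbm(background@cardinalities, 0L))
}

#' @rdname DiffRBM-class
#' @param object A [DiffRBM-class].
#' @export
backgroundModel <- function(object) object@background

#' @rdname DiffRBM-class
#' @export
differentialModel <- function(object) object@diff

#' Train the differential part on a selected dataset
#'
#' Second step of the two-step transfer learning: with the background RBM
#' frozen, the differential fields, weights and potentials are fit by
#' gradient ascent on the mean log-likelihood of the selected dataset under
#' the full model (background + differential). The model expectation in the
#' gradient is sampled from the full model by persistent chains initialized
#' from the selected data (exactly, via the independent-site closed form,
#' when both parts are fields-only). The background parameters are bitwise
#' identical before and after.
#'
#' @param background Trained [RBM-class], kept frozen.
#' @param selected Integer state matrix of selected sequences, aligned with
#'   the same cardinalities as the background.
#' @param config A [trainingConfig()]; \code{nHidden} is the number of
#'   differential units Md (0 for the fields-only "linear" variant).
#' @param weights Optional per-sequence weights.
#' @return A [DiffRBM-class].
#' @export
trainDifferential <- function(background, selected,
                              config = trainingConfig(), weights = NULL) {
  stopifnot(is(background, "RBM"))
  d <- trainRBMCore(selected, weights, config, frozen = background)
  attrd <- attr(d, "history")
  attr(d, "history") <- NULL
  out <- new("DiffRBM", background = background, diff = d)
  attr(out, "history") <- attrd
  out
}

#' Sequence scores of a diffRBM
#'
#' Log-probability scores up to model-dependent additive constants:
#' the background score \eqn{L^b = -H^b}, the differential-units score
#' \eqn{L^d = -H^d}, and the full score \eqn{L = L^b + L^d} (the identity
#' holds exactly, by construction). Only differences and rankings of scores
#' are meaningful.
#'
#' @param model A [DiffRBM-class] (or plain [RBM-class], scored as
#'   background only).
#' @param states Integer state matrix.
#' @return \code{data.frame} with columns \code{full}, \code{background},
#'   \code{diff}, one row per sequence.
#' @export
scoreSequences <- function(model, states) {
  if (is(model, "RBM")) {
    lb <- -energy(model, states)
    return(data.frame(full = lb, background = lb, diff = 0))
  }
  stopifnot(is(model, "DiffRBM"))
  lb <- -energy(model@background, states)
  ld <- -energy(model@diff, states)
  data.frame(full = lb + ld, background = lb, diff = ld)
}

#' Difference of differential scores from two models sharing a background
#'
#' \eqn{L^d(\sigma) - L^{d,neg}(\sigma)} for a positive-selected and a
#' negative-selected model trained on the identical frozen background.
#' Under a shared background this equals the difference of the full scores
#' \eqn{L - L^{neg}} exactly, which is why both models must carry the same
#' background (checked, error otherwise).
#'
#' @param modelPos,modelNeg [DiffRBM-class] models with identical
#'   backgrounds.
#' @param states Integer state matrix.
#' @return Numeric vector of score differences.
#' @export
differenceScore <- function(modelPos, modelNeg, states) {
  stopifnot(is(modelPos, "DiffRBM"), is(modelNeg, "DiffRBM"))
  if (!identical(modelPos@background, modelNeg@background))
    stop("models do not share an identical background; ",
         "the difference score identity would not hold")
  scoreSequences(modelPos, states)$diff - scoreSequences(modelNeg, states)$diff
}
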