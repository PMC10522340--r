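#' @include potentials.R alphabet.R utils.R
NULL

#' Restricted Boltzmann Machine over categorical sequence sites
#'
#' An RBM over fixed-length categorical sequences \eqn{\sigma} with per-site
#' state spaces (21 residue states at amino-acid sites; optional 48-state V
#' and 13-state J gene sites). The marginal energy is
#' \deqn{H(\sigma) = -\left(\sum_i g_i(\sigma_i) +
#'   \sum_{\mu} \Gamma_\mu(I_\mu(\sigma))\right), \quad
#'   I_\mu(\sigma) = \sum_i w_{i\mu}(\sigma_i),}
#' with fields \eqn{g}, weights \eqn{w} and per-hidden-unit cumulants
#' \eqn{\Gamma_\mu} (see [HiddenPotential-class]). Fields and weights are
#' stored flat over the concatenated per-site state spaces
#' (length \eqn{\sum_i q_i}).
#'
#' @slot fields Numeric vector, length \code{sum(cardinalities)}.
#' @slot weights Numeric matrix, \code{sum(cardinalities)} x \code{M}.
#' @slot potentials List of \code{M} [HiddenPotential-class] objects.
#' @slot cardinalities Integer vector of per-site state-space sizes.
#' @export
setClass("RBM",
         representation(fields = "numeric", weights = "matrix",
                        potentials = "list", cardinalities = "integer"))

setValidity("RBM", function(object) {
  f <- sum(object@cardinalities)
  if (length(object@fields) != f) return("fields length != sum(cardinalities)")
  if (nrow(object@weights) != f) return("weights rows != sum(cardinalities)")
  if (ncol(object@weights) != length(object@potentials))
    return("weights columns != number of potentials")
  if (!all(vapply(object@potentials, is, TRUE, class2 = "HiddenPotential")))
    return("potentials must be HiddenPotential objects")
  if (any(!is.finite(object@fields)) || any(!is.finite(object@weights)))
    return("non-finite parameters")
  TRUE
})

setMethod("show", "RBM", function(object) {
  cat(sprintf("RBM: %d sites (cardinalities %s), %d hidden unit(s)%s\n",
              length(object@cardinalities),
              paste(unique(object@cardinalities), collapse = "/"),
              nHidden(object),
              if (nHidden(object) > 0)
                sprintf(" [%s]", object@potentials[[1]]@family) else ""))
})

#' Construct an RBM with given shapes
#'
#' @param cardinalities Integer vector of per-site state-space sizes.
#' @param nHidden Number of hidden units (may be 0: independent-site model).
#' @param family Hidden-unit potential family (\code{"drelu"},
#'   \code{"gaussian"} or \code{"bernoulli"}).
#' @param fields,weights Optional initial parameters (defaults: zeros).
#' @return An [RBM-class] object.
#' @export
rbm <- function(cardinalities, nHidden = 0L, family = "drelu",
                fields = NULL, weights = NULL) {
  card <- as.integer(cardinalities)
  f <- sum(card)
  pots <- replicate(nHidden, switch(family,
    drelu = dreluPotential(), gaussian = gaussianPotential(),
    bernoulli = bernoulliPotential(),
    stop("unknown potential family: ", family)), simplify = FALSE)
  new("RBM",
      fields = fields %||% numeric(f),
      weights = weights %||% matrix(0, f, nHidden),
      potentials = pots, cardinalities = card)
}

#' @rdname rbm
#' @param object An [RBM-class] object.
#' @export
nSites <- function(object) length(object@cardinalities)

#' @rdname rbm
#' @export
nHidden <- function(object) length(object@potentials)

#' @rdname rbm
#' @export
rbmFields <- function(object) object@fields

#' @rdname rbm
#' @export
rbmWeights <- function(object) object@weights

#' @rdname rbm
#' @export
rbmPotentials <- function(object) object@potentials

# fields of site i as a named vector (residue sites named by amino acid)
fieldsAt <- function(object, site) {
  card <- object@cardinalities
  idx <- flatIndex(site, seq_len(card[site]), card)
  g <- object@fields[idx]
  if (card[site] == residueCardinality()) names(g) <- aminoAlphabet()
  g
}

#' Sequence energy under an RBM
#'
#' \eqn{H(\sigma) = -(\sum_i g_i(\sigma_i) + \sum_\mu \Gamma_\mu(I_\mu(\sigma)))}.
#' Scores used elsewhere in the package are \eqn{-H} up to model-dependent
#' constants; only differences and rankings of energies are meaningful.
#'
#' @param model An [RBM-class] (or [DiffRBM-class], for which the combined
#'   background + differential energy is returned).
#' @param states Integer state matrix ([encodeSequences()]), or a single
#'   state vector.
#' @return Numeric vector of energies, one per row of \code{states}.
#' @export
energy <- function(model, states) {
  if (is(model, "DiffRBM"))
    return(energy(model@background, states) + energy(model@diff, states))
  states <- asStateMatrix(states, model@cardinalities)
  X <- oneHot(states)
  e <- as.numeric(X %*% model@fields)
  if (nHidden(model) > 0) {
    I <- as.matrix(X %*% model@weights)
    for (mu in seq_len(nHidden(model)))
      e <- e + hiddenCGF(model@potentials[[mu]], I[, mu])
  }
  -e
}

#' Exact log partition function by enumeration
#'
#' Sums \eqn{e^{-H(\sigma)}} over the full state space; a brute-force oracle
#' usable only for small models (at most \code{maxStates} configurations).
#'
#' @param model An [RBM-class] or [DiffRBM-class].
#' @param maxStates Enumeration guard (default \code{1e6}).
#' @return \eqn{\log Z} (numeric scalar).
#' @export
exactLogPartition <- function(model, maxStates = 1e6) {
  card <- if (is(model, "DiffRBM")) model@background@cardinalities
          else model@cardinalities
  total <- prod(as.numeric(card))
  if (total > maxStates)
    stop("state space too large to enumerate: ", total, " > ", maxStates)
  grid <- as.matrix(expand.grid(lapply(card, seq_len)))
  dimnames(grid) <- NULL
  attr(grid, "cardinalities") <- card
  e <- energy(model, grid)
  m <- max(-e)
  m + log(sum(exp(-e - m)))
}

# enumerate all configurations with exact probabilities (test oracle)
enumerateStates <- function(model) {
  card <- if (is(model, "DiffRBM")) model@background@cardinalities
          else model@cardinalities
  grid <- as.matrix(expand.grid(lapply(card, seq_len)))
  dimnames(grid) <- NULL
  attr(grid, "cardinalities") <- card
  logZ <- exactLogPartition(model)
  list(states = grid, logp = -energy(model, grid) - logZ)
}

# one block-Gibbs sweep: h | sigma then sigma | h.
# fullFields/fullWeights/fullPots describe the distribution actually sampled
# (for a DiffRBM these concatenate background and differential parts).
gibbsSweep <- function(states, card, fullFields, fullWeights, fullPots) {
  n <- nrow(states)
  X <- oneHot(asStateMatrix(states, card))
  M <- length(fullPots)
  if (M > 0) {
    I <- as.matrix(X %*% fullWeights)
    H <- matrix(0, n, M)
    for (mu in seq_len(M)) H[, mu] <- sampleHidden(fullPots[[mu]], I[, mu])
    logits <- matrix(fullFields, n, length(fullFields), byrow = TRUE) +
      H %*% t(fullWeights)
  } else {
    logits <- matrix(fullFields, n, length(fullFields), byrow = TRUE)
  }
  off <- c(0L, cumsum(card))
  out <- states
  for (i in seq_along(card)) {
    block <- logits[, (off[i] + 1L):off[i + 1L], drop = FALSE]
    gmb <- -log(-log(matrix(runif(length(block)), nrow(block))))
    out[, i] <- max.col(block + gmb, ties.method = "first")
  }
  out
}

#' Sample sequences from an RBM by block Gibbs sampling
#'
#' Alternates sampling of all hidden units given the sequence and of all
#' sites given the hidden units. Reproducible under a fixed seed. For a
#' [DiffRBM-class] the combined (background + differential) distribution is
#' sampled.
#'
#' @param model An [RBM-class] or [DiffRBM-class].
#' @param n Number of sequences (independent parallel chains).
#' @param steps Gibbs sweeps per chain (burn-in; the final state is returned).
#' @param seed Integer seed.
#' @param init Optional integer state matrix of initial chain states
#'   (\code{n} rows); default: uniform random states.
#' @return Integer state matrix with \code{cardinalities} attribute.
#' @export
gibbsSample <- function(model, n, steps = 100, seed = 1, init = NULL) {
  stopifnot(n >= 1, steps >= 1)
  pr <- combinedParams(model)
  card <- pr$card
  set.seed(seed)
  if (is.null(init)) {
    states <- vapply(card, function(q) sample.int(q, n, replace = TRUE),
                     integer(n))
    if (n == 1L) states <- matrix(states, nrow = 1L)
  } else {
    states <- asStateMatrix(init, card)
    stopifnot(nrow(states) == n)
  }
  for (s in seq_len(steps))
    states <- gibbsSweep(states, card, pr$fields, pr$weights, pr$pots)
  asStateMatrix(states, card)
}

# flatten an RBM or DiffRBM into one set of sampling parameters
combinedParams <- function(model) {
  if (is(model, "DiffRBM")) {
    bg <- model@background; d <- model@diff
    list(card = bg@cardinalities,
         fields = bg@fields + d@fields,
         weights = cbind(bg@weights, d@weights),
         pots = c(bg@potentials, d@potentials))
  } else {
    list(card = model@cardinalities, fields = model@fields,
         weights = model@weights, pots = model@potentials)
  }
}

#' Training configuration
#'
#' Hyperparameters for [trainBackground()] and [trainDifferential()].
#' \code{l21} is the squared-L1 weight penalty
#' \eqn{(\lambda_{2,1}/(2q)) \sum_\mu (\sum_{i,a} |w_{i\mu}(a)|)^2}
#' with \eqn{q} the residue cardinality; it drives whole hidden units towards
#' sparse, localized weights. Defaults follow the peptide-model setting
#' (10 hidden units, \eqn{\lambda_{2,1}} = 0.001).
#'
#' @param nHidden Number of hidden units M (0 gives the fields-only model).
#' @param l21 Nonnegative squared-L1 weight penalty.
#' @param family Potential family for the hidden units.
#' @param learningRate ADAM step size at the first epoch.
#' @param finalLearningRate Step size reached (geometrically) at the last
#'   epoch; default \code{learningRate / 10}. The decay lets the optimizer
#'   settle close to the optimum instead of hovering at the minibatch noise
#'   floor.
#' @param minibatch Minibatch size.
#' @param epochs Training epochs.
#' @param nChains Persistent chains (default: minibatch size).
#' @param gibbsSteps Gibbs sweeps per parameter update.
#' @param seed Master seed (controls initialization, minibatching, chains).
#' @param pseudocount Pseudocount for the field initialization from data
#'   frequencies.
#' @return A list of class \code{"trainingConfig"}.
#' @export
trainingConfig <- function(nHidden = 10L, l21 = 0.001, family = "drelu",
                           learningRate = 5e-3, finalLearningRate = NULL,
                           minibatch = 100L,
                           epochs = 500L, nChains = NULL, gibbsSteps = 10L,
                           seed = 1L, pseudocount = 0.01) {
  stopifnot(nHidden >= 0, l21 >= 0, learningRate > 0, epochs >= 1,
            minibatch >= 1, gibbsSteps >= 1)
  structure(list(nHidden = as.integer(nHidden), l21 = l21, family = family,
                 learningRate = learningRate,
                 finalLearningRate = finalLearningRate %||%
                   (learningRate / 10),
                 minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs),
                 nChains = as.integer(nChains %||% minibatch),
                 gibbsSteps = as.integer(gibbsSteps),
                 seed = as.integer(seed), pseudocount = pseudocount),
            class = "trainingConfig")
}

#' Train the background RBM by (weighted) maximum likelihood
#'
#' Stochastic gradient ascent on the weighted mean log-likelihood of the
#' aligned dataset, with the squared-L1 weight penalty of
#' [trainingConfig()]. The model expectation in the gradient is estimated
#' with persistent contrastive divergence (persistent Gibbs chains,
#' Rao-Blackwellized hidden means); for fields-only models (M = 0) the
#' model expectation is computed exactly from the independent-site closed
#' form. A zero-sum gauge over states at each site is applied to fields and
#' weights after training, for identifiability of reported parameters.
#'
#' @param data Integer state matrix ([encodeSequences()] /
#'   [alignSequences()]).
#' @param weights Optional per-sequence positive weights
#'   ([similarityReweight()]); default uniform.
#' @param config A [trainingConfig()].
#' @return A trained [RBM-class] with attribute \code{"history"} (mean
#'   weighted training energy per monitoring interval).
#' @export
trainBackground <- function(data, weights = NULL, config = trainingConfig()) {
  trainRBMCore(data, weights, config, frozen = NULL)
}

# weighted sufficient statistics of the log-likelihood gradient wrt the
# trainable parameters: d/dg = E[1hot], d/dw = E[1hot * Gamma'(I)],
# d/dxi = E[dGamma/dxi(I)]. Used for both the data term and (with chain or
# enumeration weights) the model term.
suffStats <- function(W, pots, X, wts) {
  wts <- wts / sum(wts)
  M <- length(pots)
  G <- as.numeric(Matrix::crossprod(X, wts))
  if (M == 0L) return(list(G = G, W = NULL, P = NULL))
  I <- as.matrix(X %*% W)
  hmean <- matrix(0, nrow(X), M)
  P <- matrix(0, M, length(pots[[1]]@params))
  for (mu in seq_len(M)) {
    hmean[, mu] <- hiddenMean(pots[[mu]], I[, mu])
    P[mu, ] <- colSums(hiddenGradStats(pots[[mu]], I[, mu]) * wts)
  }
  colnames(P) <- names(pots[[1]]@params)
  list(G = G, W = as.matrix(Matrix::crossprod(X, hmean * wts)), P = P)
}

# shared PCD trainer; `frozen` is the fixed background part for differential
# training (NULL for background training). Trainable parameters are always
# the (fields, weights, potentials) of the returned RBM.
trainRBMCore <- function(data, weights, config, frozen = NULL) {
  stopifnot(inherits(config, "trainingConfig"))
  states <- asStateMatrix(data)
  card <- cardinalities(states)
  if (!is.null(frozen)) {
    if (!identical(as.integer(frozen@cardinalities), card))
      stop("selected data cardinalities do not match the background model")
  }
  n <- nrow(states)
  if (n == 0L) stop("empty training data")
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w > 0))
  M <- config$nHidden
  F <- sum(card)
  qres <- residueCardinality()
  set.seed(config$seed)

  X <- oneHot(states)
  wn <- w / sum(w)
  fdata <- as.numeric(Matrix::crossprod(X, wn))      # weighted 1-hot freqs

  # init: fields at (pseudocounted) log data frequencies, small random weights
  g <- log(fdata + config$pseudocount / rep(card, card))
  for (i in seq_along(card)) {
    idx <- flatIndex(i, seq_len(card[i]), card)
    g[idx] <- g[idx] - mean(g[idx])
  }
  if (!is.null(frozen)) g <- numeric(F)               # differential: start at 0
  W <- matrix(rnorm(F * M, sd = 0.01), F, M)
  pots <- replicate(M, switch(config$family,
    drelu = dreluPotential(), gaussian = gaussianPotential(),
    bernoulli = bernoulliPotential()), simplify = FALSE)
  npar <- if (M > 0) length(pots[[1]]@params) else 0L
  P <- if (M > 0) t(vapply(pots, function(p) p@params, numeric(npar)))
       else matrix(0, 0, 0)

  frozenM <- if (is.null(frozen)) 0L else nHidden(frozen)
  exactModel <- (M == 0L && frozenM == 0L)
  fg <- if (is.null(frozen)) numeric(F) else frozen@fields

  nChains <- min(config$nChains, n)
  if (!exactModel)
    chains <- states[sample.int(n, nChains, replace = nChains > n), ,
                     drop = FALSE]

  adam <- function() list(m = 0, v = 0)
  stG <- adam(); stW <- adam(); stP <- adam()
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  adamStep <- function(st, grad, rate) {
    st$m <- b1 * st$m + (1 - b1) * grad
    st$v <- b2 * st$v + (1 - b2) * grad^2
    mh <- st$m / (1 - b1^t); vh <- st$v / (1 - b2^t)
    st$delta <- rate * mh / (sqrt(vh) + eps)
    st
  }
  rebuildPots <- function(P) lapply(seq_len(M), function(mu) {
    p <- pots[[mu]]; p@params[] <- P[mu, ]; p
  })

  history <- numeric(0)
  nb <- max(1L, ceiling(n / config$minibatch))
  for (epoch in seq_len(config$epochs)) {
    rate <- if (config$epochs == 1L) config$learningRate
      else config$learningRate *
        (config$finalLearningRate / config$learningRate)^
          ((epoch - 1) / (config$epochs - 1))
    ord <- sample.int(n)
    for (b in seq_len(nb)) {
      idx <- ord[(((b - 1L) * config$minibatch) + 1L):
                   min(b * config$minibatch, n)]
      Xb <- X[idx, , drop = FALSE]
      wb <- w[idx] / sum(w[idx])
      t <- t + 1

      # data term
      ds <- suffStats(W, pots, Xb, wb)
      dG <- ds$G; dW <- ds$W; gpdata <- ds$P

      # model term
      if (exactModel) {
        logits <- fg + g
        pmodel <- numeric(F)
        for (i in seq_along(card)) {
          ii <- flatIndex(i, seq_len(card[i]), card)
          z <- logits[ii] - max(logits[ii])
          pmodel[ii] <- exp(z) / sum(exp(z))
        }
        mG <- pmodel
      } else {
        fullW <- if (is.null(frozen)) W else cbind(frozen@weights, W)
        fullP <- if (is.null(frozen)) pots else c(frozen@potentials, pots)
        for (s in seq_len(config$gibbsSteps))
          chains <- gibbsSweep(chains, card, fg + g, fullW, fullP)
        Xc <- oneHot(asStateMatrix(chains, card))
        ms <- suffStats(W, pots, Xc, rep(1, nChains))
        mG <- ms$G; mW <- ms$W; gpmodel <- ms$P
      }

      gradG <- dG - mG
      stG <- adamStep(stG, gradG, rate)
      g <- g + stG$delta

      if (M > 0) {
        s1 <- colSums(abs(W))                      # per-unit L1 norms
        pen <- (config$l21 / qres) *
          sweep(sign(W), 2L, s1, `*`)
        gradW <- dW - mW - pen
        stW <- adamStep(stW, gradW, rate)
        W <- W + stW$delta
        gradP <- gpdata - gpmodel
        stP <- adamStep(stP, gradP, rate)
        P <- P + stP$delta
        gi <- grep("gamma", colnames(hiddenGradStats(pots[[1]], 0)))
        P[, gi] <- pmax(P[, gi], 0.05)
        pots <- rebuildPots(P)
      }

      if (any(!is.finite(g)) || (M > 0 && any(!is.finite(W))))
        stop("training diverged: non-finite parameters at update ", t)
    }
    if (epoch %% 25L == 0L || epoch == config$epochs) {
      # fields-only proxy of the training energy, cheap monitoring signal
      history <- c(history, sum(w / sum(w) * energy(
        new("RBM", fields = fg + g, weights = matrix(0, F, 0),
            potentials = list(), cardinalities = card), states)))
    }
  }

  out <- new("RBM", fields = g, weights = W, potentials = pots,
             cardinalities = card)
  out <- zeroSumGauge(out)
  attr(out, "history") <- history
  out
}

# exact log-likelihood gradient wrt the trainable part (test oracle support:
# same sufficient-statistics code as training, model term by enumeration)
exactLikelihoodGradient <- function(trainable, states, frozen = NULL) {
  card <- trainable@cardinalities
  states <- asStateMatrix(states, card)
  full <- if (is.null(frozen)) trainable
          else new("DiffRBM", background = frozen, diff = trainable)
  en <- enumerateStates(full)
  ds <- suffStats(trainable@weights, trainable@potentials,
                  oneHot(states), rep(1, nrow(states)))
  ms <- suffStats(trainable@weights, trainable@potentials,
                  oneHot(en$states), exp(en$logp))
  list(G = ds$G - ms$G,
       W = if (is.null(ds$W)) NULL else ds$W - ms$W,
       P = if (is.null(ds$P)) NULL else ds$P - ms$P)
}

#' Apply the zero-sum gauge
#'
#' Shifts fields and weights so they sum to zero over states at each site
#' (weight shifts are compensated exactly by translating the hidden-unit
#' potentials), leaving the probability distribution unchanged up to a
#' constant. Makes single-site parameters comparable across positions.
#'
#' @param model An [RBM-class].
#' @return The gauged [RBM-class].
#' @export
zeroSumGauge <- function(model) {
  card <- model@cardinalities
  g <- model@fields; W <- model@weights; pots <- model@potentials
  shift <- numeric(ncol(W))
  for (i in seq_along(card)) {
    idx <- flatIndex(i, seq_len(card[i]), card)
    g[idx] <- g[idx] - mean(g[idx])
    if (ncol(W) > 0) {
      mw <- colMeans(W[idx, , drop = FALSE])
      W[idx, ] <- sweep(W[idx, , drop = FALSE], 2L, mw)
      shift <- shift + mw
    }
  }
  if (length(pots) > 0)
    pots <- lapply(seq_along(pots),
                   function(mu) shiftPotential(pots[[mu]], shift[mu]))
  new("RBM", fields = g, weights = W, potentials = pots,
      cardinalities = card)
}
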