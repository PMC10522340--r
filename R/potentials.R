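#' Hidden-unit potentials
#'
#' S4 class describing the potential \eqn{U(h)} of one real- or binary-valued
#' hidden unit. Three families are supported:
#' \describe{
#'   \item{gaussian}{\eqn{U(h) = \gamma h^2/2 + \theta h}, \eqn{\gamma > 0}.}
#'   \item{bernoulli}{\eqn{h \in \{0,1\}}, \eqn{U(h) = \theta h}.}
#'   \item{drelu}{double rectified linear unit,
#'     \eqn{U(h) = \gamma_+ h_+^2/2 + \gamma_- h_-^2/2 + \theta_+ h_+ + \theta_- h_-}
#'     with \eqn{h_+ = \max(h,0)}, \eqn{h_- = \max(-h,0)} and
#'     \eqn{\gamma_\pm > 0}; the default family for trained models, able to
#'     represent asymmetric, sparse hidden-unit activities.}
#' }
#' The cumulant \eqn{\Gamma(I) = \log \int dh\, e^{-U(h) + hI}} and its
#' derivative (the conditional mean activity) are available in closed form
#' for every family via [hiddenCGF()] and [hiddenMean()].
#'
#' @slot family Character, one of \code{"gaussian"}, \code{"bernoulli"},
#'   \code{"drelu"}.
#' @slot params Named numeric vector of family-specific parameters.
#' @export
setClass("HiddenPotential",
         representation(family = "character", params = "numeric"))

setValidity("HiddenPotential", function(object) {
  f <- object@family
  p <- object@params
  if (!f %in% c("gaussian", "bernoulli", "drelu"))
    return("unknown potential family")
  need <- switch(f,
    gaussian = c("gamma", "theta"),
    bernoulli = "theta",
    drelu = c("gamma_plus", "gamma_minus", "theta_plus", "theta_minus"))
  if (!all(need %in% names(p)))
    return(paste("missing parameters:", paste(setdiff(need, names(p)),
                                              collapse = ", ")))
  if (any(!is.finite(p))) return("non-finite potential parameters")
  if (f == "gaussian" && p[["gamma"]] <= 0)
    return("gaussian curvature gamma must be positive")
  if (f == "drelu" &&
      (p[["gamma_plus"]] <= 0 || p[["gamma_minus"]] <= 0))
    return("dReLU curvatures must be positive")
  TRUE
})

setMethod("show", "HiddenPotential", function(object) {
  cat(sprintf("HiddenPotential [%s] %s\n", object@family,
              paste(sprintf("%s=%.3g", names(object@params), object@params),
                    collapse = " ")))
})

#' @rdname HiddenPotential-class
#' @param gamma,theta Gaussian curvature (>0) and tilt.
#' @export
gaussianPotential <- function(gamma = 1, theta = 0) {
  new("HiddenPotential", family = "gaussian",
      params = c(gamma = gamma, theta = theta))
}

#' @rdname HiddenPotential-class
#' @export
bernoulliPotential <- function(theta = 0) {
  new("HiddenPotential", family = "bernoulli", params = c(theta = theta))
}

#' @rdname HiddenPotential-class
#' @param gammaPlus,gammaMinus,thetaPlus,thetaMinus dReLU curvatures (>0)
#'   and per-branch tilts.
#' @export
dreluPotential <- function(gammaPlus = 1, gammaMinus = 1,
                           thetaPlus = 0, thetaMinus = 0) {
  new("HiddenPotential", family = "drelu",
      params = c(gamma_plus = gammaPlus, gamma_minus = gammaMinus,
                 theta_plus = thetaPlus, theta_minus = thetaMinus))
}

# dReLU branch statistics shared by CGF, mean and gradients.
# Positive branch: h ~ N(b+/g+, 1/g+) truncated to h > 0, b+ = I - theta+.
# Negative branch: h = -u, u ~ N(b-/g-, 1/g-) truncated to u > 0,
# b- = -(I + theta-).
dreluStats <- function(p, I) {
  gp <- p[["gamma_plus"]]; gm <- p[["gamma_minus"]]
  bp <- I - p[["theta_plus"]]
  bm <- -(I + p[["theta_minus"]])
  ap <- bp / sqrt(gp); am <- bm / sqrt(gm)
  lp <- bp^2 / (2 * gp) + 0.5 * log(2 * pi / gp) + pnorm(ap, log.p = TRUE)
  lm <- bm^2 / (2 * gm) + 0.5 * log(2 * pi / gm) + pnorm(am, log.p = TRUE)
  cgf <- logsumexp2(lp, lm)
  wp <- exp(lp - cgf)                       # probability of positive branch
  rp <- millsRatioInv(ap); rm <- millsRatioInv(am)
  mup <- bp / gp; mum <- bm / gm
  sp <- 1 / sqrt(gp); sm <- 1 / sqrt(gm)
  eup <- mup + sp * rp                      # E[u | branch], u > 0
  eum <- mum + sm * rm
  eup2 <- mup^2 + sp^2 + mup * sp * rp      # E[u^2 | branch]
  eum2 <- mum^2 + sm^2 + mum * sm * rm
  list(cgf = cgf, wp = wp, eup = eup, eum = eum, eup2 = eup2, eum2 = eum2,
       mup = mup, mum = mum, sp = sp, sm = sm)
}

#' Hidden-unit cumulant generating function
#'
#' \eqn{\Gamma(I) = \log \int dh\, e^{-U(h) + hI}}, the per-unit contribution
#' to the marginal sequence energy, evaluated in closed form. Vectorized
#' over \code{I}.
#'
#' @param pot A [HiddenPotential-class] object.
#' @param I Numeric vector of inputs \eqn{I = \sum_i w_i(\sigma_i)}.
#' @return Numeric vector, \eqn{\Gamma(I)}.
#' @export
hiddenCGF <- function(pot, I) {
  stopifnot(is(pot, "HiddenPotential"), all(is.finite(I)))
  p <- pot@params
  switch(pot@family,
    gaussian = (I - p[["theta"]])^2 / (2 * p[["gamma"]]) +
      0.5 * log(2 * pi / p[["gamma"]]),
    bernoulli = log1p(exp(-abs(I - p[["theta"]]))) +
      pmax(I - p[["theta"]], 0),            # log(1 + e^{I-theta}), stable
    drelu = dreluStats(p, I)$cgf)
}

#' Conditional mean hidden-unit activity
#'
#' \eqn{\Gamma'(I)}, the mean of \eqn{h} under the conditional density
#' \eqn{\propto e^{-U(h) + hI}}; nondecreasing in \code{I} (convexity of
#' \eqn{\Gamma}). Vectorized over \code{I}.
#'
#' @inheritParams hiddenCGF
#' @return Numeric vector, \eqn{\langle h | I \rangle}.
#' @export
hiddenMean <- function(pot, I) {
  stopifnot(is(pot, "HiddenPotential"), all(is.finite(I)))
  p <- pot@params
  switch(pot@family,
    gaussian = (I - p[["theta"]]) / p[["gamma"]],
    bernoulli = plogis(I - p[["theta"]]),
    drelu = {
      s <- dreluStats(p, I)
      s$wp * s$eup - (1 - s$wp) * s$eum
    })
}

# d Gamma / d params, one column per parameter; used in training.
hiddenGradStats <- function(pot, I) {
  p <- pot@params
  switch(pot@family,
    gaussian = {
      m <- (I - p[["theta"]]) / p[["gamma"]]
      eh2 <- 1 / p[["gamma"]] + m^2
      cbind(gamma = -eh2 / 2, theta = -m)
    },
    bernoulli = cbind(theta = -plogis(I - p[["theta"]])),
    drelu = {
      s <- dreluStats(p, I)
      ehp <- s$wp * s$eup; ehp2 <- s$wp * s$eup2
      ehm <- (1 - s$wp) * s$eum; ehm2 <- (1 - s$wp) * s$eum2
      cbind(gamma_plus = -ehp2 / 2, gamma_minus = -ehm2 / 2,
            theta_plus = -ehp, theta_minus = -ehm)
    })
}

# sample h | I for a vector of inputs (one draw each)
sampleHidden <- function(pot, I) {
  p <- pot@params
  n <- length(I)
  switch(pot@family,
    gaussian = rnorm(n, mean = (I - p[["theta"]]) / p[["gamma"]],
                     sd = 1 / sqrt(p[["gamma"]])),
    bernoulli = as.numeric(runif(n) < plogis(I - p[["theta"]])),
    drelu = {
      s <- dreluStats(p, I)
      pos <- runif(n) < s$wp
      u <- numeric(n)
      # inverse-CDF draw from the positive-mean-truncated normal of each branch
      drawTrunc <- function(mu, sigma) {
        p0 <- pnorm(0, mu, sigma)
        q <- qnorm(p0 + runif(length(mu)) * (1 - p0), mu, sigma)
        bad <- !is.finite(q) | q < 0
        if (any(bad)) q[bad] <- pmax(mu[bad], 0)  # deep-tail fallback
        q
      }
      mup <- rep_len(s$mup, n); mum <- rep_len(s$mum, n)
      if (any(pos)) u[pos] <- drawTrunc(mup[pos], s$sp)
      if (any(!pos)) u[!pos] <- -drawTrunc(mum[!pos], s$sm)
      u
    })
}

# translate the potential so that Gamma_new(I) = Gamma_old(I + c);
# used by the zero-sum gauge on weights.
shiftPotential <- function(pot, c) {
  p <- pot@params
  switch(pot@family,
    gaussian = { p[["theta"]] <- p[["theta"]] - c },
    bernoulli = { p[["theta"]] <- p[["theta"]] - c },
    drelu = {
      p[["theta_plus"]] <- p[["theta_plus"]] - c
      p[["theta_minus"]] <- p[["theta_minus"]] + c
    })
  new("HiddenPotential", family = pot@family, params = p)
}
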