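#' Planted differential-model scenario
#'
#' Builds a synthetic study: a background RBM with seeded random
#' parameters, plus a differential perturbation (fields, and weights when
#' \code{Md > 0}) concentrated on designated "contact-like" focus
#' positions and scaled by \code{strength}. At \code{strength = 0} the
#' selected distribution is exactly the background distribution. Defaults
#' mirror the peptide setting: 9 residue sites, 21 states, a 10-hidden-unit
#' background, a fields-only differential part perturbing the central
#' positions 4-8 (the positions typically contacted by the TCR).
#'
#' @param nSites Number of residue sites (default 9).
#' @param cardinality States per site (default 21).
#' @param Mb Background hidden units (default 10).
#' @param Md Differential hidden units (default 0: fields-only planted
#'   signal).
#' @param strength Scale of the differential perturbation (>= 0).
#' @param focusPositions Sites carrying the perturbation (default 4:8).
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @param family Potential family of planted hidden units (default
#'   \code{"gaussian"}, which keeps the planted model analytically
#'   convenient).
#' @return List of class \code{"plantedScenario"}: \code{background}
#'   ([RBM-class]), \code{model} ([DiffRBM-class]), \code{focusPositions},
#'   \code{strength}, \code{seed}.
#' @export
makeScenario <- function(nSites = 9L, cardinality = 21L, Mb = 10L, Md = 0L,
                         strength = 1, focusPositions = 4:8, seed = 1L,
                         family = "gaussian") {
  stopifnot(nSites >= 1, cardinality >= 2, Mb >= 0, Md >= 0, strength >= 0,
            all(focusPositions >= 1), all(focusPositions <= nSites))
  card <- rep(as.integer(cardinality), nSites)
  nF <- sum(card)
  set.seed(seed)
  bg <- rbm(card, Mb, family = family,
            fields = rnorm(nF, sd = 0.5),
            weights = matrix(rnorm(nF * Mb, sd = 0.2 / sqrt(nSites)),
                             nF, Mb))
  bg <- zeroSumGauge(bg)
  gd <- numeric(nF)
  wd <- matrix(0, nF, Md)
  for (i in focusPositions) {
    idx <- flatIndex(i, seq_len(card[i]), card)
    gd[idx] <- strength * rnorm(card[i])
    if (Md > 0)
      wd[idx, ] <- strength * matrix(rnorm(card[i] * Md, sd = 0.3),
                                     card[i], Md)
  }
  d <- rbm(card, Md, family = family, fields = gd, weights = wd)
  d <- zeroSumGauge(d)
  if (strength == 0) {                      # exact null: no perturbation
    d@fields[] <- 0
    d@weights[] <- 0
  }
  structure(list(background = bg, model = diffRBM(bg, d),
                 focusPositions = as.integer(focusPositions),
                 strength = strength, seed = as.integer(seed)),
            class = "plantedScenario")
}

#' Sample background and selected datasets from a planted scenario
#'
#' Background sequences are drawn from the background model and selected
#' sequences from the combined (background + differential) model, by
#' parallel Gibbs chains with burn-in. Mimics the size asymmetry of real
#' studies (background much larger than selected).
#'
#' @param scenario A [makeScenario()] result.
#' @param nBackground,nSelected Sample sizes (defaults 4000 and 1600,
#'   matching the largest peptide study arm).
#' @param seed Integer seed.
#' @param burnin Gibbs sweeps before taking the sample (default 100).
#' @return List with state matrices \code{background} and \code{selected}.
#' @export
sampleScenario <- function(scenario, nBackground = 4000L, nSelected = 1600L,
                           seed = 1L, burnin = 100L) {
  stopifnot(inherits(scenario, "plantedScenario"),
            nBackground >= 1, nSelected >= 1)
  list(background = gibbsSample(scenario$background, nBackground,
                                steps = burnin, seed = deriveSeed(seed, 1L)),
       selected = gibbsSample(scenario$model, nSelected,
                              steps = burnin, seed = deriveSeed(seed, 2L)))
}

#' Toy contact fixtures from a planted scenario
#'
#' Samples sequences from the selected model and declares their contact
#' sets to be the scenario's focus positions (optionally jittered by one
#' position). When \code{dir} is given, writes one minimal PDB file per
#' entry with the peptide as C-alpha-like pseudo-atoms on a line 8 A
#' apart (chain P) and partner pseudo-atoms (chain T) placed 3 A from each
#' contact position, so that [computeContacts()] at the 4 A cutoff
#' recovers exactly the declared contacts.
#'
#' @param scenario A [makeScenario()] result.
#' @param nStructures Number of fixture entries.
#' @param seed Integer seed.
#' @param jitter Probability of displacing each contact by one position.
#' @param dir Optional output directory for PDB files.
#' @return \code{data.frame} of contact entries (\code{structure},
#'   \code{sequence}, \code{contacts} list column, \code{path} if files
#'   were written).
#' @export
makeContactFixtures <- function(scenario, nStructures = 10L, seed = 1L,
                                jitter = 0, dir = NULL) {
  stopifnot(inherits(scenario, "plantedScenario"))
  nSites <- nSites(scenario$background)
  states <- gibbsSample(scenario$model, nStructures, steps = 100,
                        seed = deriveSeed(seed, 3L))
  # structures carry real residues only: replace any sampled gap state
  states[states == gapIndex()] <- 1L
  seqs <- decodeSequences(states)
  set.seed(deriveSeed(seed, 4L))
  entries <- lapply(seq_len(nStructures), function(k) {
    contacts <- scenario$focusPositions
    if (jitter > 0) {
      move <- runif(length(contacts)) < jitter
      contacts[move] <- pmin(pmax(contacts[move] +
                                    sample(c(-1L, 1L), sum(move),
                                           replace = TRUE), 1L), nSites)
      contacts <- sort(unique(contacts))
    }
    list(id = sprintf("synthetic_%03d", k), contacts = contacts)
  })
  out <- data.frame(structure = vapply(entries, `[[`, "", "id"),
                    sequence = seqs)
  out$contacts <- I(lapply(entries, `[[`, "contacts"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path <- vapply(seq_len(nStructures), function(k)
      writeFixturePDB(file.path(dir, paste0(entries[[k]]$id, ".pdb")),
                      seqs[k], entries[[k]]$contacts), character(1))
  }
  out
}

# minimal single-conformer PDB: peptide CA atoms on the x-axis, partner
# pseudo-atoms 3 A above each contact position
writeFixturePDB <- function(path, seq1, contacts) {
  aa3 <- vapply(strsplit(seq1, "")[[1]], bio3d::aa123, character(1))
  lines <- character(0)
  serial <- 0L
  atomLine <- function(serial, name, res3, chain, resno, x, y, z, elem) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, res3, chain, resno, x, y, z, 1, 0, elem)
  }
  for (i in seq_along(aa3)) {
    serial <- serial + 1L
    lines <- c(lines, atomLine(serial, "CA", aa3[i], "P", i,
                               8 * i, 0, 0, "C"))
  }
  for (k in seq_along(contacts)) {
    serial <- serial + 1L
    lines <- c(lines, atomLine(serial, "CA", "GLY", "T", k,
                               8 * contacts[k], 3, 0, "C"))
  }
  writeLines(c(lines, "END"), path)
  path
}

#' Synthetic mutational-assay table
#'
#' Emulates a mutational scanning of a 9-mer wild-type peptide: for each
#' TCR, every position is mutated to each of the other 19 amino acids
#' (171 mutants). Mutations at \code{lethalPositions} are marked lethal
#' (no EC50); other mutants receive
#' \eqn{EC50^{MT} = EC50^{WT} \exp(cost + noise)} where \code{cost} is the
#' background-factor predicted cost of the mutation under the planted
#' model, so at zero noise the experimental and predicted costs agree
#' exactly.
#'
#' @param scenario A [makeScenario()] result.
#' @param tcrCount Number of TCRs (default 3).
#' @param lethalPositions Positions whose mutations are lethal.
#' @param seed Integer seed.
#' @param noise Standard deviation of the log-EC50 noise (default 0).
#' @param wtStates Optional wild-type state vector (default: one draw from
#'   the selected model).
#' @return \code{data.frame}: \code{tcr_id}, \code{position}, \code{wt},
#'   \code{mt}, \code{ec50_wt}, \code{ec50_mt}, \code{lethal}.
#' @export
makeAssayTable <- function(scenario, tcrCount = 3L,
                           lethalPositions = integer(0), seed = 1L,
                           noise = 0, wtStates = NULL) {
  stopifnot(inherits(scenario, "plantedScenario"))
  card <- scenario$background@cardinalities
  if (is.null(wtStates)) {
    wtStates <- gibbsSample(scenario$model, 1L, steps = 100,
                            seed = deriveSeed(seed, 5L))
    # a wild type must carry no gaps (mutants substitute residues)
    wtStates[wtStates == gapIndex()] <- 1L
  }
  wt <- asStateMatrix(wtStates, card)
  alpha <- aminoAlphabet()
  nSites <- length(card)
  set.seed(deriveSeed(seed, 6L))
  rows <- list()
  for (tcr in seq_len(tcrCount)) {
    for (i in seq_len(nSites)) {
      wtA <- alpha[wt[1L, i]]
      for (a in setdiff(seq_len(20L), wt[1L, i])) {
        lethal <- i %in% lethalPositions
        cost <- predictedCost(scenario$model, wt, i, alpha[a],
                              source = "background")
        ec50mt <- if (lethal) NA_real_
                  else exp(cost + if (noise > 0) rnorm(1, sd = noise) else 0)
        rows[[length(rows) + 1L]] <-
          data.frame(tcr_id = sprintf("TCR%d", tcr), position = i,
                     wt = wtA, mt = alpha[a], ec50_wt = 1,
                     ec50_mt = ec50mt, lethal = lethal)
      }
    }
  }
  do.call(rbind, rows)
}
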