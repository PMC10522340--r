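# small seeded models and datasets shared across tests

smallRBM <- function(card = c(3L, 2L, 3L), M = 1L, family = "drelu",
                     seed = 1, sd = 0.4) {
  set.seed(seed)
  f <- sum(card)
  rbm(card, M, family = family, fields = rnorm(f, sd = sd),
      weights = matrix(rnorm(f * M, sd = sd), f, M))
}

smallDiffRBM <- function(card = c(3L, 2L, 3L), Mb = 1L, Md = 1L,
                         family = "drelu", seed = 1, sd = 0.4) {
  bg <- smallRBM(card, Mb, family, seed, sd)
  d <- smallRBM(card, Md, family, seed + 100, sd)
  diffRBM(bg, d)
}

smallStates <- function(card = c(3L, 2L, 3L), n = 6L, seed = 2) {
  set.seed(seed)
  s <- vapply(card, function(q) sample.int(q, n, replace = TRUE), integer(n))
  attr(s, "cardinalities") <- card
  storage.mode(s) <- "integer"
  s
}

# quadrature oracle for the hidden-unit cumulant and its mean
quadCGF <- function(U, I) {
  z <- stats::integrate(function(h) exp(-U(h) + h * I), -60, 60,
                        rel.tol = 1e-12)$value
  log(z)
}
quadMean <- function(U, I) {
  z <- stats::integrate(function(h) exp(-U(h) + h * I), -60, 60,
                        rel.tol = 1e-12)$value
  m <- stats::integrate(function(h) h * exp(-U(h) + h * I), -60, 60,
                        rel.tol = 1e-12)$value
  m / z
}

dreluU <- function(gp, gm, tp, tm) {
  function(h) gp * pmax(h, 0)^2 / 2 + gm * pmax(-h, 0)^2 / 2 +
    tp * pmax(h, 0) + tm * pmax(-h, 0)
}

# exact mean log-likelihood of data under a small (enumerable) model
exactMeanLogLik <- function(model, states) {
  mean(-energy(model, states)) - exactLogPartition(model)
}

writeFixtureCIF <- function(path, seq1, contacts) {
  aa3 <- vapply(strsplit(seq1, "")[[1]], bio3d::aa123, character(1))
  hdr <- c("data_synthetic", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id",
                    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                    "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                    "auth_seq_id", "auth_comp_id", "auth_asym_id",
                    "auth_atom_id", "pdbx_PDB_model_num")))
  row <- function(id, res3, chain, ent, resno, x, y, z)
    sprintf("ATOM %d C CA . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
            id, res3, chain, ent, resno, x, y, z, resno, res3, chain)
  lines <- character(0)
  id <- 0L
  for (i in seq_along(aa3)) {
    id <- id + 1L
    lines <- c(lines, row(id, aa3[i], "P", 1L, i, 8 * i, 0, 0))
  }
  for (k in seq_along(contacts)) {
    id <- id + 1L
    lines <- c(lines, row(id, "GLY", "T", 2L, k, 8 * contacts[k], 3, 0))
  }
  writeLines(c(hdr, lines), path)
  path
}
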