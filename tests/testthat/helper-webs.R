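# Toy webs and independent oracles used across the suite.

# producer -> herbivore chain; optionally a detritus pool and landings
toy_chain <- function(herb_b = 0.1, herb_qb = 10, herb_pb = 1,
                      prod_b = 1, prod_pb = 10, landings = c(0, 0),
                      unassim = 0.2, detritus = TRUE) {
  n <- 2L + detritus
  g <- data.frame(
    name = c("Herbivore", "Plant", if (detritus) "Detritus"),
    type = c("consumer", "producer", if (detritus) "detritus"),
    biomass = c(herb_b, prod_b, if (detritus) 1),
    pb = c(herb_pb, prod_pb, if (detritus) NA),
    qb = c(herb_qb, NA, if (detritus) NA),
    ee = NA_real_,
    landings = c(landings, if (detritus) 0),
    unassim = c(unassim, 0, if (detritus) 0),
    stringsAsFactors = FALSE)
  d <- matrix(0, n, n)
  d[2L, 1L] <- 1
  food_web_model(g, d)
}

# three-layer chain with a mid-level omnivore option
toy_three_level <- function(top_diet = c(mid = 1, bottom = 0)) {
  g <- data.frame(
    name = c("Top", "Mid", "Plant", "Detritus"),
    type = c("consumer", "consumer", "producer", "detritus"),
    biomass = c(0.01, 0.5, 10, 1),
    pb = c(1, 5, 80, NA), qb = c(5, 20, NA, NA),
    ee = NA_real_, landings = 0, stringsAsFactors = FALSE)
  d <- matrix(0, 4L, 4L)
  d[2L, 1L] <- top_diet[["mid"]]
  d[3L, 1L] <- top_diet[["bottom"]]
  d[3L, 2L] <- 1
  food_web_model(g, d)
}

# brute-force mass-balance oracle: nonlinear root-finding on the raw
# residuals of the per-group balance, independent of the linear solver
oracle_balance <- function(model) {
  g <- model$groups
  qb <- ifelse(g$type == "consumer" & !is.na(g$qb), g$qb, 0)
  ex <- g$landings + g$ba + g$migration
  liv <- which(g$type != "detritus")
  ub <- which(is.na(g$biomass))
  ue <- intersect(which(is.na(g$ee)), liv)
  unknowns <- c(ub, ue)
  resid <- function(x) {
    b <- g$biomass; e <- g$ee
    b[ub] <- x[seq_along(ub)]
    e[ue] <- x[length(ub) + seq_along(ue)]
    pred <- as.vector(model$diet %*% (b * qb))
    (b * g$pb * e - pred - ex)[liv]
  }
  start <- c(rep(1, length(ub)), rep(0.5, length(ue)))
  sol <- pracma::fsolve(resid, start, maxiter = 400)$x
  b <- g$biomass; e <- g$ee
  b[ub] <- sol[seq_along(ub)]
  e[ue] <- sol[length(ub) + seq_along(ue)]
  list(biomass = b, ee = e)
}

# truncated walk-sum oracle for the Leontief diagonal used by the
# cycling index: Q = sum_k G^k instead of a matrix inversion
oracle_fci <- function(net, kmax = 400L) {
  T_j <- net$throughflow
  n <- length(T_j)
  G <- matrix(0, n, n)
  pos <- T_j > 0
  G[, pos] <- sweep(net$flows[, pos, drop = FALSE], 2L, T_j[pos], "/")
  Q <- diag(n); P <- diag(n)
  for (k in seq_len(kmax)) { P <- P %*% G; Q <- Q + P }
  qd <- diag(Q)
  cycled <- sum(T_j * (qd - 1) / qd)
  det <- net$types == "detritus"
  tst <- sum(net$throughflow[net$types == "consumer"]) +
    sum(net$exports) + sum(net$respiration) + sum(net$throughflow[det])
  100 * cycled / tst
}

# truncated path-sum oracle for the mixed-trophic-impact matrix
oracle_mti <- function(q, kmax = 300L) {
  n <- nrow(q)
  M <- matrix(0, n, n, dimnames = dimnames(q)); P <- diag(n)
  for (k in seq_len(kmax)) { P <- P %*% q; M <- M + P }
  M
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g",
                              actual, tol, expected))
}
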