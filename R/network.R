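#' Assemble the flow network of a balanced model
#'
#' Collects every term of the balanced model into an explicit
#' compartment-flow representation: internal flows `prey -> predator`
#' (`B_j (Q/B)_j DC_ij`) plus each group's flow to the detritus pool;
#' boundary imports (gross primary production entering at the producers,
#' plus any imported diet); boundary exports (fishery landings per group
#' and the unconsumed detritus surplus); and respiration. Per-compartment
#' throughflow is intake for consumers, production for producers and total
#' inflow for detritus; summed over compartments it equals the total
#' system throughput.
#'
#' @param bal a `balanced_web`.
#' @return object of class `flow_network` with elements `flows` (n x n
#'   matrix), `imports`, `exports`, `respiration`, `throughflow`, `types`.
#' @export
build_flow_network <- function(bal) {
  model <- bal$model
  s <- bal$stats
  g <- model$groups
  n <- nrow(g)
  cons <- g$type == "consumer"
  det <- which(g$type == "detritus")
  consumption <- ifelse(cons, s$consumption, 0)
  flows <- sweep(model$diet, 2L, consumption, "*")   # prey -> predator
  fd <- ifelse(is.na(s$flow_to_detritus), 0, s$flow_to_detritus)
  # flows to detritus are split across pools by their share of biomass
  dshare <- g$biomass[det] / sum(g$biomass[det])
  for (k in seq_along(det)) flows[, det[k]] <- flows[, det[k]] +
    fd * dshare[k]
  # boundary imports are imported diet fractions only: primary production
  # is generated inside the system (it is the producers' throughflow, and
  # reaches the network through their outflows), not a trans-boundary flow
  imports <- model$import * consumption
  exports <- g$landings + pmax(g$ba, 0)
  det_in <- colSums(flows[, det, drop = FALSE])
  det_out <- rowSums(sweep(model$diet[det, , drop = FALSE], 2L,
                           consumption, "*"))
  surplus <- det_in - det_out
  if (any(surplus < -1e-9))
    warning("detritus pool over-consumed (negative export): ",
            paste(g$name[det][surplus < 0], collapse = ", "))
  exports[det] <- exports[det] + surplus
  respiration <- ifelse(cons, s$respiration, 0)
  throughflow <- ifelse(cons, consumption,
                 ifelse(g$type == "producer", s$production, det_in))
  structure(list(flows = flows, imports = imports, exports = exports,
                 respiration = respiration, throughflow = throughflow,
                 types = g$type, names = g$name),
            class = "flow_network")
}

#' Whole-system summary statistics
#'
#' Computes the standard ecosystem-level indicators of a balanced model:
#' the throughput decomposition (total consumption, exports, respiration,
#' flows into detritus, and their sum TST), production totals (TP, TNPP,
#' NSP), maturity ratios (TPP/TR, TPP/TB, TB/TST), catch statistics (total
#' catch, gross efficiency, mean trophic level of the catch), structure
#' indices (connectance, system omnivory, Shannon diversity of living
#' biomass), and the cycling measures of [finn_cycling()] and information
#' measures of [ascendancy()].
#'
#' Convention choices (documented here because published values differ by
#' small amounts between software versions): connectance is the number of
#' realised predator-prey links divided by `N_living^2`
#' (`ci_method = "links_nliving_sq"`), with the directed-graph alternative
#' `L / (N (N - 1))` available; the system omnivory index is the mean of
#' consumer omnivory indices weighted by the logarithm of each consumer's
#' consumption; Shannon diversity uses natural logarithms.
#'
#' @param net a [build_flow_network()] result.
#' @param bal the corresponding `balanced_web`.
#' @param ci_method connectance convention, see Details.
#' @return object of class `system_summary` (a named list of scalars).
#' @export
system_summary <- function(net, bal,
                           ci_method = c("links_nliving_sq",
                                         "links_n_nminus1")) {
  ci_method <- match.arg(ci_method)
  s <- bal$stats
  g <- bal$model$groups
  cons <- g$type == "consumer"
  liv <- g$type != "detritus"
  det <- g$type == "detritus"

  total_consumption <- sum(s$consumption[cons])
  total_exports <- sum(net$exports)
  total_respiration <- sum(s$respiration[cons])
  total_fd <- bal$detritus_inflow
  tst <- total_consumption + total_exports + total_respiration + total_fd
  total_production <- sum(s$production[liv])
  tnpp <- sum(s$production[g$type == "producer"])
  nsp <- tnpp - total_respiration
  tb <- sum(g$biomass[liv])
  total_catch <- sum(g$landings)
  mtlc <- if (total_catch > 0)
    sum(g$landings * s$tl) / total_catch else NA_real_
  p <- g$biomass[liv] / tb
  shannon <- -sum(p * log(p))

  links <- sum(bal$model$diet[, cons] > 0)
  n_liv <- sum(liv)
  ci <- switch(ci_method,
    links_nliving_sq = links / n_liv^2,
    links_n_nminus1 = links / (nrow(g) * (nrow(g) - 1)))
  w <- log(s$consumption[cons])
  soi <- sum(s$oi[cons] * w) / sum(w)

  cyc <- finn_cycling(net)
  asc <- ascendancy(net)

  structure(list(
    total_consumption = total_consumption, total_exports = total_exports,
    total_respiration = total_respiration,
    total_flows_to_detritus = total_fd, tst = tst,
    total_production = total_production, tnpp = tnpp, nsp = nsp,
    tpp_tr = tnpp / total_respiration, tpp_tb = tnpp / tb,
    tb_tst = tb / tst, total_biomass = tb, total_catch = total_catch,
    mtlc = mtlc, gross_efficiency = total_catch / tnpp, shannon = shannon,
    ci = ci, soi = soi,
    fci_percent = cyc$fci_percent,
    throughput_cycled = cyc$throughput_cycled, fmpl = cyc$fmpl,
    ascendancy_percent = asc$ascendancy_percent,
    overhead_percent = asc$overhead_percent, capacity = asc$capacity),
    class = "system_summary")
}

#' @export
print.system_summary <- function(x, ...) {
  df <- as.data.frame(x)
  print(data.frame(parameter = df$parameter,
                   value = signif(df$value, 6)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.system_summary <- function(x, ...) {
  data.frame(parameter = names(unclass(x)),
             value = as.numeric(unlist(x)), stringsAsFactors = FALSE)
}

#' Finn's cycling index and mean path length
#'
#' Input-output (Leontief) analysis of the flow network: with `G` the
#' matrix of direct inflow fractions (`G_ij = T_ij / T_j`, the share of
#' compartment j's throughflow arriving directly from i) the integral
#' matrix `Q = (I - G)^-1` counts all direct and indirect pathways. The
#' diagonal `q_jj` exceeds 1 exactly when material leaving j returns to j,
#' and `(q_jj - 1) / q_jj` of j's throughflow is cycled. The cycling index
#' is the cycled fraction of total system throughput (in percent);
#' the mean path length is TST divided by the total boundary outflow
#' (exports plus respiration) -- the average number of compartments a unit
#' of flow traverses before leaving.
#'
#' @param net a [build_flow_network()] result.
#' @return list with `fci_percent`, `throughput_cycled`, `fmpl`, and the
#'   per-compartment cycled throughflow `cycled`.
#' @export
finn_cycling <- function(net) {
  T_j <- net$throughflow
  n <- length(T_j)
  G <- matrix(0, n, n, dimnames = dimnames(net$flows))
  pos <- T_j > 0
  G[, pos] <- sweep(net$flows[, pos, drop = FALSE], 2L, T_j[pos], "/")
  Q <- tryCatch(solve(diag(n) - G), error = function(e)
    stop("singular structure matrix in cycling analysis: ",
         conditionMessage(e), call. = FALSE))
  qd <- diag(Q)
  cycled <- ifelse(qd > 0, T_j * (qd - 1) / qd, 0)
  # TST as the standard decomposition: consumption + exports +
  # respiration + detritus inflow
  det <- net$types == "detritus"
  tst <- sum(net$throughflow[net$types == "consumer"]) +
    sum(net$exports) + sum(net$respiration) + sum(net$throughflow[det])
  list(fci_percent = 100 * sum(cycled) / tst,
       throughput_cycled = sum(cycled),
       fmpl = tst / (sum(net$exports) + sum(net$respiration)),
       cycled = cycled)
}

#' Ascendancy, overhead and development capacity
#'
#' Information-theoretic flow indices on the network extended
#' with three boundary compartments (one import source, one export sink,
#' one dissipation sink). Ascendancy
#' `A = sum T_ij log2(T_ij T.. / (T_i. T._j))` measures how determined the
#' flow structure is; capacity `C = -sum T_ij log2(T_ij / T..)` bounds it;
#' overhead `O = C - A` is the system's redundancy in reserve. Both are
#' returned as percentages of capacity (base-invariant and scale-invariant).
#'
#' @param net a [build_flow_network()] result.
#' @return list with `ascendancy_percent`, `overhead_percent`, `capacity`
#'   (flow-bits), and absolute `ascendancy`/`overhead`.
#' @export
ascendancy <- function(net) {
  n <- length(net$throughflow)
  m <- n + 3L
  Tm <- matrix(0, m, m)
  Tm[seq_len(n), seq_len(n)] <- net$flows
  Tm[n + 1L, seq_len(n)] <- net$imports
  Tm[seq_len(n), n + 2L] <- net$exports
  Tm[seq_len(n), n + 3L] <- net$respiration
  tot <- sum(Tm)
  ri <- rowSums(Tm); cj <- colSums(Tm)
  idx <- which(Tm > 0, arr.ind = TRUE)
  tij <- Tm[idx]
  a <- sum(tij * log2(tij * tot / (ri[idx[, 1L]] * cj[idx[, 2L]])))
  cap <- -sum(tij * log2(tij / tot))
  list(ascendancy_percent = 100 * a / cap,
       overhead_percent = 100 * (cap - a) / cap,
       capacity = cap, ascendancy = a, overhead = cap - a)
}

#' Pedigree index scaffold
#'
#' Data-quality (pedigree) scoring for model inputs: given user-supplied
#' per-parameter confidence scores in [0, 1] (one row per group, columns
#' such as biomass, P/B, Q/B, diet, catch), the pedigree index is their
#' overall mean and the associated fit measure is
#' `t* = P sqrt(n - 2) / sqrt(1 - P^2)` with `n` the number of living
#' groups. No scores are bundled for the Kaptai model because the
#' originating study does not publish them; this scaffold exists so users
#' can score their own inputs.
#'
#' @param scores numeric matrix or data frame of scores in [0, 1].
#' @return list with `pedigree` and `t_star`.
#' @export
pedigree_index <- function(scores) {
  sc <- as.matrix(scores)
  if (any(sc < 0 | sc > 1, na.rm = TRUE))
    stop("pedigree scores must lie in [0, 1]")
  p <- mean(sc, na.rm = TRUE)
  n <- nrow(sc)
  list(pedigree = p, t_star = p * sqrt(n - 2) / sqrt(1 - p^2))
}
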