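#' Automatic mass-balancing by iterative diet adjustment
#'
#' When the solved model leaves some groups with EE > 1 (demand exceeding
#' production), the standard remedy is to shave the offending prey out of
#' the diets that drive the over-consumption. Each iteration takes the
#' worst offender `k` (largest EE, ties by group order), finds the
#' predator whose consumption contributes most to predation on `k`,
#' reduces that diet entry by `step_fraction` of its value, and
#' redistributes the removed proportion across the predator's other prey
#' `j` with weights `(DC_j_max - DC_j_mean) / sum(...)`, where max and
#' mean are taken over that prey's realised diet entries across all
#' predators in the current matrix (prey with headroom below their
#' observed maximum absorb more). Diet columns therefore remain exactly
#' column-stochastic, and each predator's total consumption is untouched
#' -- only its composition moves. Iteration stops when every EE <= 1 or
#' `max_iter` is reached.
#'
#' @param model a solvable [food_web_model()].
#' @param max_iter iteration cap.
#' @param step_fraction fraction of the offending diet link removed per
#'   iteration.
#' @return list with `model` (edited), `balanced` (the final
#'   `balanced_web`), and `audit`: class `balance_audit` holding
#'   `iterations`, `converged`, an `edits` data frame (iteration,
#'   predator, prey reduced, amount moved, EE before) and `ee_trajectory`.
#' @export
auto_balance <- function(model, max_iter = 200L, step_fraction = 0.1) {
  stopifnot(step_fraction > 0, step_fraction < 1)
  edits <- list()
  traj <- list()
  it <- 0L
  converged <- FALSE
  repeat {
    bal <- balance_model(model)
    s <- bal$stats
    liv <- s$type != "detritus"
    off <- which(liv & s$ee > 1 + 1e-9)
    traj[[it + 1L]] <- stats::setNames(s$ee, s$name)
    if (length(off) == 0L) { converged <- TRUE; break }
    if (it >= max_iter) break
    it <- it + 1L
    off <- off[order(-s$ee[off], off)]
    k <- off[1L]
    # predator contributing most to predation on k
    cons <- model$groups$type == "consumer"
    # unknown-B predators enter the ranking with their solved biomass
    bsolved <- bal$model$groups$biomass
    contrib <- bsolved * ifelse(cons, model$groups$qb, 0) * model$diet[k, ]
    contrib[is.na(contrib)] <- 0
    j <- which.max(contrib)
    if (contrib[j] <= 0) break      # nothing edible to edit: give up
    others <- which(model$diet[, j] > 0 & seq_len(nrow(s)) != k)
    if (length(others) == 0L) {
      warning("predator ", s$name[j], " has a single prey; cannot ",
              "redistribute its diet away from ", s$name[k])
      break
    }
    delta <- step_fraction * model$diet[k, j]
    # redistribution weights: headroom of each alternative prey relative
    # to its observed maximum share across predators
    dmax <- apply(model$diet[, cons, drop = FALSE], 1L, max)
    dbar <- rowMeans(model$diet[, cons, drop = FALSE])
    w <- pmax(dmax[others] - dbar[others], 0)
    if (sum(w) == 0) w <- model$diet[others, j]
    w <- w / sum(w)
    model$diet[k, j] <- model$diet[k, j] - delta
    model$diet[others, j] <- model$diet[others, j] + delta * w
    edits[[it]] <- data.frame(iteration = it, predator = s$name[j],
                              prey_reduced = s$name[k],
                              amount = delta, ee_before = s$ee[k],
                              stringsAsFactors = FALSE)
  }
  audit <- structure(list(iterations = it, converged = converged,
                          edits = if (length(edits)) do.call(rbind, edits)
                                  else data.frame(),
                          ee_trajectory = traj),
                     class = "balance_audit")
  if (!converged)
    warning("auto_balance did not converge within ", max_iter,
            " iterations; returning best model so far")
  list(model = model, balanced = bal, audit = audit)
}

#' @export
print.balance_audit <- function(x, ...) {
  cat("balance_audit:", x$iterations, "iteration(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (nrow(x$edits) > 0L) print(utils::head(x$edits, 10L), row.names = FALSE)
  invisible(x)
}
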