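#' Solve the steady-state mass balance of a food web
#'
#' For every living group i the model enforces
#' `B_i * (P/B)_i * EE_i = sum_j B_j * (Q/B)_j * DC_ij + EX_i`,
#' i.e. production is consumed by predators, removed by the fishery
#' (`EX`, landings plus biomass accumulation and net migration) or lost to
#' other mortality. Each group supplies either its biomass or its
#' ecotrophic efficiency; the missing one is solved for. The equation is
#' linear in every unknown biomass (including cannibalism terms on the
#' diagonal), so all unknown biomasses are obtained in a single linear
#' solve and unknown efficiencies follow by substitution -- the result is
#' independent of group order.
#'
#' Groups whose solved EE falls outside [0, 1] do not abort the solve: the
#' returned object carries `balanced = FALSE` and names the offending
#' groups, so that [auto_balance()] can act on them.
#'
#' @param model a validated [food_web_model()].
#' @return an object of class `balanced_web`: the input model with all
#'   parameters filled, a per-group statistics table (see
#'   [derived_statistics()]), the detritus ecotrophic efficiency, and
#'   balance flags.
#' @export
balance_model <- function(model) {
  validate_model(model, require_detritus = FALSE)
  g <- model$groups
  n <- nrow(g)
  qb <- ifelse(g$type == "consumer" & !is.na(g$qb), g$qb, 0)
  ex <- g$landings + g$ba + g$migration
  liv <- which(g$type != "detritus")
  unknown_b <- which(is.na(g$biomass))
  if (length(bad <- setdiff(unknown_b, liv)) > 0L)
    stop("detritus biomass must be supplied (group ",
         paste(g$name[bad], collapse = ", "), ")")

  b <- g$biomass
  if (length(unknown_b) > 0L) {
    # linear system A x = r in the unknown biomasses
    A <- matrix(0, length(unknown_b), length(unknown_b),
                dimnames = list(g$name[unknown_b], g$name[unknown_b]))
    r <- numeric(length(unknown_b))
    known <- setdiff(seq_len(n), unknown_b)
    for (a in seq_along(unknown_b)) {
      i <- unknown_b[a]
      A[a, ] <- -qb[unknown_b] * model$diet[i, unknown_b]
      A[a, a] <- A[a, a] + g$pb[i] * g$ee[i]
      r[a] <- sum(b[known] * qb[known] * model$diet[i, known]) + ex[i]
    }
    x <- tryCatch(solve(A, r), error = function(e)
      stop("mass balance is structurally unsolvable for group(s) ",
           paste(g$name[unknown_b], collapse = ", "),
           " (singular system: ", conditionMessage(e), ")", call. = FALSE))
    if (any(x <= 0))
      warning("solved biomass is non-positive for group(s): ",
              paste(g$name[unknown_b[x <= 0]], collapse = ", "))
    b[unknown_b] <- x
  }

  consumption <- b * qb
  predation <- as.vector(model$diet %*% consumption)  # flow out of each prey
  ee <- g$ee
  fill <- which(is.na(ee) & g$type != "detritus")
  production <- ifelse(g$type != "detritus", b * g$pb, NA_real_)
  ee[fill] <- (predation[fill] + ex[fill]) / production[fill]

  filled <- model
  filled$groups$biomass <- b
  filled$groups$ee <- ee

  bal <- structure(list(model = filled, stats = NULL,
                        detritus_inflow = NA_real_, balanced = NA,
                        unbalanced_groups = character()),
                   class = "balanced_web")
  bal <- derived_statistics(bal)
  off <- with(bal$stats, name[type != "detritus" &
                                (ee > 1 + 1e-9 | ee < -1e-9)])
  bal$balanced <- length(off) == 0L
  bal$unbalanced_groups <- off
  bal
}

#' Per-group derived statistics of a balanced model
#'
#' Completes the per-group accounting of a solved model. For a consumer
#' with unassimilated fraction `GS`: assimilation `A = Q (1 - GS)`,
#' respiration `R = A - P`, net efficiency `NE = P/A`, and flow to
#' detritus `FD = GS Q + (1 - EE) P` (egestion plus other mortality). A
#' producer sends `FD = (1 - EE) P` to detritus and respires nothing here
#' (P/B is taken as net production). Detritus has no production of its
#' own; its "production" for efficiency purposes is its total inflow
#' `sum(FD)`, and its EE is the fraction of that inflow consumed by
#' detritivores. Fractional trophic levels and omnivory indices are
#' attached as well.
#'
#' A consumer with `P > A` (negative respiration) is thermodynamically
#' inconsistent and is flagged in `$flags$negative_respiration`.
#'
#' @param bal a `balanced_web` (called for its side table; [balance_model()]
#'   calls this automatically).
#' @return `bal` with `$stats` filled: one row per group with columns
#'   `tl`, `biomass`, `pb`, `qb`, `ee`, `pq`, `production`, `consumption`,
#'   `assimilation`, `respiration`, `predation`, `landings`,
#'   `flow_to_detritus`, `ne`, `pr`, `ra`, `oi`.
#' @export
derived_statistics <- function(bal) {
  model <- bal$model
  g <- model$groups
  cons <- g$type == "consumer"
  det <- g$type == "detritus"
  qb <- ifelse(cons, g$qb, 0)
  b <- g$biomass
  production <- ifelse(det, NA_real_, b * g$pb)
  consumption <- b * qb
  predation <- as.vector(model$diet %*% consumption)
  assimilation <- ifelse(cons, consumption * (1 - g$unassim), NA_real_)
  respiration <- ifelse(cons, assimilation - production, NA_real_)
  fd <- ifelse(cons, g$unassim * consumption + (1 - g$ee) * production,
        ifelse(det, 0, (1 - g$ee) * production))
  inflow <- sum(fd, na.rm = TRUE)
  ee <- g$ee
  ee[det] <- if (inflow > 0) predation[det] / inflow else 0

  tl <- trophic_levels(model$diet, g$type, import = model$import)
  oi <- omnivory_index(model$diet, tl, g$type)

  bal$stats <- data.frame(
    name = g$name, type = g$type, tl = tl, biomass = b, pb = g$pb,
    qb = g$qb, ee = ee,
    pq = ifelse(cons, production / consumption, NA_real_),
    production = production, consumption = ifelse(cons, consumption,
                                                  NA_real_),
    assimilation = assimilation, respiration = respiration,
    predation = predation, landings = g$landings,
    flow_to_detritus = fd,
    ne = ifelse(cons, production / assimilation, NA_real_),
    pr = ifelse(cons, production / respiration, NA_real_),
    ra = ifelse(cons, respiration / assimilation, NA_real_),
    oi = oi, stringsAsFactors = FALSE)
  bal$model$groups$ee <- ee
  bal$detritus_inflow <- inflow
  bal$flags <- list(
    negative_respiration = g$name[cons & !is.na(respiration) &
                                    respiration < -1e-12])
  if (length(bal$flags$negative_respiration) > 0L)
    warning("negative respiration (P > A), thermodynamically ",
            "inconsistent group(s): ",
            paste(bal$flags$negative_respiration, collapse = ", "))
  bal
}

#' Ecotrophic efficiency of the detritus pool
#'
#' The fraction of all flows into detritus (egestion plus other mortality
#' of every group) that is consumed by detritivores; the remainder leaves
#' the system as detritus export (burial/accumulation).
#'
#' @param bal a `balanced_web`.
#' @return a single fraction.
#' @export
detritus_ee <- function(bal) {
  det <- detritus_idx(bal$model)
  if (bal$detritus_inflow <= 0) stop("detritus pool receives no inflow")
  sum(bal$stats$predation[det]) / bal$detritus_inflow
}

#' @export
print.balanced_web <- function(x, ...) {
  cat("balanced_web:", nrow(x$stats), "groups;",
      if (isTRUE(x$balanced)) "all EE within [0, 1]"
      else paste("UNBALANCED:", paste(x$unbalanced_groups, collapse = ", ")),
      "\n")
  s <- x$stats
  show <- data.frame(group = s$name, TL = round(s$tl, 3),
                     B = signif(s$biomass, 4), EE = round(s$ee, 3),
                     FD = signif(s$flow_to_detritus, 5))
  print(show, row.names = FALSE)
  invisible(x)
}
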