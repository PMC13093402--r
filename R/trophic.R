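#' Fractional trophic levels
#'
#' Producers and detritus are pinned at trophic level 1; every consumer
#' sits one level above the diet-weighted mean of its prey:
#' `TL_i = 1 + sum_q DC_qi TL_q`. The fixed point is obtained by one exact
#' linear solve (no iteration-order dependence); cannibalism and
#' consumer-consumer cycles are handled by the matrix inverse. Imported
#' diet fractions are treated as level-1 food.
#'
#' @param diet diet matrix, prey rows x predator columns.
#' @param types character vector of group types.
#' @param import optional imported diet fraction per predator.
#' @return numeric vector of trophic levels.
#' @export
trophic_levels <- function(diet, types, import = NULL) {
  n <- length(types)
  if (is.null(import)) import <- numeric(n)
  cons <- which(types == "consumer")
  tl <- rep(1, n)
  if (length(cons) == 0L) return(tl)
  W <- diet[cons, cons, drop = FALSE]          # prey x predator, consumers
  base <- colSums(diet[-cons, cons, drop = FALSE] * 1) + import[cons]
  A <- diag(length(cons)) - t(W)
  rhs <- 1 + base
  tlc <- tryCatch(solve(A, rhs), error = function(e)
    stop("trophic levels are undefined: consumer diet cycle without a ",
         "level-1 anchor (singular system)", call. = FALSE))
  tl[cons] <- tlc
  tl
}

#' Omnivory index
#'
#' The diet-weighted variance of prey trophic levels,
#' `OI_i = sum_q DC_qi (TL_q - (TL_i - 1))^2`. Zero for a specialist
#' feeding on a single trophic level; large for consumers spreading their
#' diet across levels.
#'
#' @inheritParams trophic_levels
#' @param tl trophic levels as returned by [trophic_levels()].
#' @return numeric vector, zero for producers and detritus.
#' @export
omnivory_index <- function(diet, tl, types) {
  n <- length(types)
  oi <- numeric(n)
  for (i in which(types == "consumer")) {
    dc <- diet[, i]
    oi[i] <- sum(dc * (tl - (tl[i] - 1))^2)
  }
  oi
}

#' Decompose each group's flows onto integer trophic levels
#'
#' The standard flow-fraction recursion: a producer or detritus pool is
#' 100% level 1; the fraction of a consumer's intake attributable to level
#' `k+1` is the diet-weighted sum of its prey's level-`k` fractions. Diet
#' columns are normalised to sum to one so that each group's fractions sum
#' to 1 exactly; cycles (cannibalism, detritus loops in the consumer part)
#' decay geometrically and the recursion is carried far enough that the
#' truncated tail is below 1e-12 before being folded into the top level.
#'
#' @inheritParams trophic_levels
#' @param max_level number of integer levels to report; higher-level tail
#'   mass is folded into `max_level`.
#' @param drop_self drop cannibalism loops (diagonal diet entries) and
#'   renormalise, as trophic-aggregation analysis conventionally does: a
#'   group's self-consumption is not a transfer between levels. Default
#'   TRUE.
#' @return list with `fractions` (groups x levels matrix, rows summing to
#'   1), and `origin`: a list of two such matrices partitioning the
#'   fractions by ultimate source (`producer` and `detritus` pathways).
#' @export
tl_fractions <- function(diet, types, max_level = 7L, import = NULL,
                         drop_self = TRUE) {
  n <- length(types)
  if (is.null(import)) import <- numeric(n)
  cons <- types == "consumer"
  if (drop_self) diag(diet) <- 0
  dcn <- diet
  cs <- colSums(diet) + import
  dcn[, cons] <- sweep(diet[, cons, drop = FALSE], 2L, cs[cons], "/")
  impn <- ifelse(cons, import / cs, 0)

  run <- function(level1) {       # level1: starting mass per group
    K <- max(max_level, 4L)
    f <- matrix(0, n, K)
    f[, 1L] <- level1
    repeat {
      for (k in 2:K) {
        f[, k] <- 0
        f[cons, k] <- as.vector(t(dcn[, cons, drop = FALSE]) %*% f[, k - 1L])
      }
      # imported food counts as level-1 intake of the consumer
      tail_ok <- max(f[, K]) < 1e-12
      if (tail_ok || K > 60L) break
      f <- cbind(f, matrix(0, n, K))
      K <- ncol(f)
    }
    f
  }
  lvl1_all <- ifelse(cons, 0, 1)
  f <- run(lvl1_all)
  f[cons, 2L] <- f[cons, 2L] + impn[cons]   # imports enter at level 2 intake
  fp <- run(ifelse(types == "producer", 1, 0))
  fd <- run(ifelse(types == "detritus", 1, 0))
  fp[cons, 2L] <- fp[cons, 2L] + impn[cons] # imports booked as producer-origin
  fold <- function(m) {
    out <- m[, seq_len(max_level), drop = FALSE]
    if (ncol(m) > max_level)
      out[, max_level] <- out[, max_level] +
        rowSums(m[, -seq_len(max_level), drop = FALSE])
    colnames(out) <- as.roman(seq_len(max_level))
    rownames(out) <- rownames(diet)
    out
  }
  list(fractions = fold(f),
       origin = list(producer = fold(fp), detritus = fold(fd)))
}

#' Aggregate a balanced web onto the Lindeman spine
#'
#' Apportions every flow of the balanced model (consumption, catches,
#' respiration, flows to detritus) onto integer trophic levels using the
#' flow fractions of [tl_fractions()]: a consumer's intake from prey
#' attributed to level `k` enters level `k+1`. Producers and the detritus
#' pool jointly form level I. Transfer efficiency at a level is the
#' fraction of the throughput entering it that is either passed on to the
#' next level or removed by the fishery/exports (respiration and detritus
#' losses are the inefficiency). Producer-origin and detritus-origin
#' pathways are tracked separately throughout.
#'
#' @param bal a `balanced_web`.
#' @param max_level top integer level reported.
#' @return object of class `lindeman_spine`: a per-level table with
#'   throughput, flow to the next level, exports plus catch, respiration,
#'   flow to detritus, biomass and TE (in percent), the same tables
#'   restricted to producer-origin and detritus-origin flows, and the
#'   fraction of total system throughflow of detritus origin.
#' @export
lindeman_spine <- function(bal, max_level = 7L) {
  model <- bal$model
  s <- bal$stats
  g <- model$groups
  n <- nrow(g)
  cons <- g$type == "consumer"
  det <- g$type == "detritus"
  fr <- tl_fractions(model$diet, g$type, max_level = max_level,
                     import = model$import)

  # cannibalism is not a between-level transfer: intake and predation
  # are counted net of self-loops, matching the self-loop-free fractions
  self_flow <- ifelse(cons, s$consumption, 0) * diag(model$diet)
  consumption <- ifelse(cons, s$consumption, 0) - self_flow
  predflow <- s$predation - self_flow     # external predation on each prey
  ex <- g$landings + g$ba + g$migration
  resp <- ifelse(cons, s$respiration, 0)
  fd <- ifelse(is.na(s$flow_to_detritus), 0, s$flow_to_detritus)
  det_surplus <- bal$detritus_inflow - sum(predflow[det])
  # compartment throughflow: intake for consumers, production for
  # producers, total inflow for detritus
  thr <- ifelse(cons, consumption,
         ifelse(det, bal$detritus_inflow, s$production))

  level_table <- function(f) {
    L <- ncol(f)
    inflow <- numeric(L)
    inflow[1L] <- sum(thr * f[, 1L])
    for (k in 2:L) inflow[k] <- sum(consumption * f[, k])
    to_next <- vapply(seq_len(L), function(k)
      sum(predflow * f[, k]), numeric(1))
    # consumption *of* level-k material becomes level-(k+1) inflow; the
    # top level's onward flow is zero by construction of the fold
    exports <- vapply(seq_len(L), function(k) sum(ex * f[, k]), numeric(1))
    exports[1L] <- exports[1L] + det_surplus * f[which(det)[1L], 1L]
    respiration <- vapply(seq_len(L), function(k)
      sum(resp * f[, k]), numeric(1))
    to_det <- vapply(seq_len(L), function(k) sum(fd * f[, k]), numeric(1))
    biomass <- vapply(seq_len(L), function(k)
      sum(g$biomass * f[, k]), numeric(1))
    te <- ifelse(inflow > 0, 100 * (to_next + exports) / inflow, NA_real_)
    te[1L] <- NA_real_                   # efficiency undefined at the base
    data.frame(level = seq_len(L), throughput = inflow,
               flow_to_next = to_next, export_catch = exports,
               respiration = respiration, flow_to_detritus = to_det,
               biomass = biomass, te_percent = te)
  }

  all_tab <- level_table(fr$fractions)
  prod_tab <- level_table(fr$origin$producer)
  det_tab <- level_table(fr$origin$detritus)
  detritus_fraction <- sum(thr * rowSums(fr$origin$detritus)) / sum(thr)

  structure(list(levels = all_tab, producer = prod_tab,
                 detritus = det_tab, fractions = fr,
                 detritus_fraction = detritus_fraction,
                 detritus_surplus = det_surplus),
            class = "lindeman_spine")
}

#' @export
print.lindeman_spine <- function(x, ...) {
  cat("Lindeman spine (levels I-", nrow(x$levels), "), detritus-origin ",
      "fraction of throughflow ", round(x$detritus_fraction, 3), "\n",
      sep = "")
  print(cbind(round(x$levels[, 1:7], 3),
              TE = round(x$levels$te_percent, 3)), row.names = FALSE)
  invisible(x)
}

#' Transfer-efficiency table by trophic level and flow origin
#'
#' Tabulates transfer efficiency (percent) for levels II and up,
#' separately for producer-origin flows, detritus-origin flows, and all
#' flows, together with a summary mean TE per row: the geometric mean over
#' a configurable range of levels (II-IV by default, the energetically
#' dominant part of the spine).
#'
#' @param spine a [lindeman_spine()] result.
#' @param mean_levels integer levels entering the geometric-mean summary.
#' @return matrix with rows `producer`, `detritus`, `all` and one column
#'   per level plus `mean`.
#' @export
transfer_efficiency_table <- function(spine, mean_levels = 2:4) {
  rows <- list(producer = spine$producer, detritus = spine$detritus,
               all = spine$levels)
  L <- nrow(spine$levels)
  out <- matrix(NA_real_, 3L, L - 1L + 1L,
                dimnames = list(names(rows),
                                c(as.character(as.roman(2:L)), "mean")))
  for (r in seq_along(rows)) {
    te <- rows[[r]]$te_percent[-1L]
    out[r, seq_len(L - 1L)] <- te
    gm <- rows[[r]]$te_percent[mean_levels]
    out[r, "mean"] <- exp(mean(log(gm[gm > 0])))
  }
  out
}
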