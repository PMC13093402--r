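#' Mixed trophic impact matrix
#'
#' Net direct-plus-indirect impact of a marginal biomass increase of each
#' group (and optionally the fishing fleet) on every other group. The
#' direct net impact of j on i is `q_ji = DC_ji - FC_ij`: the benefit i
#' derives from j as food minus the pressure j exerts on i as a predator,
#' where `FC_ij` is the fraction of all predation-plus-catch on i taken by
#' j. The full impact matrix accumulates all pathways:
#' `MTI = (I - q)^-1 - I`, equivalently `sum_{k>=1} q^k` when the spectral
#' radius of `q` is below one. The fleet enters as an extra consumer whose
#' "diet" is the landings composition and whose "predation" is the catch.
#'
#' @param bal a `balanced_web`.
#' @param include_fleet add the fishing fleet as an extra compartment.
#' @return object of class `impact_result` with elements `mti`
#'   (impacting groups in rows, impacted in columns), `epsilon`,
#'   `relative_total_impact`, `keystoneness` (see [keystone_analysis()]),
#'   and `q` (the direct-impact matrix).
#' @export
mti_matrix <- function(bal, include_fleet = TRUE) {
  model <- bal$model
  s <- bal$stats
  g <- model$groups
  n <- nrow(g)
  cons <- g$type == "consumer"
  consumption <- ifelse(cons, s$consumption, 0)
  flows <- sweep(model$diet, 2L, consumption, "*")   # prey x predator
  landings <- g$landings
  m <- if (include_fleet) n + 1L else n
  nm <- c(g$name, if (include_fleet) "Fleet")

  # DC[i, j]: share of prey i in predator j's diet (fleet: landings share)
  DC <- matrix(0, m, m, dimnames = list(nm, nm))
  DC[seq_len(n), seq_len(n)] <- model$diet
  if (include_fleet && sum(landings) > 0)
    DC[seq_len(n), m] <- landings / sum(landings)

  # FC[i, j]: share of total predation + catch on prey i taken by j
  denom <- s$predation + landings
  FC <- matrix(0, m, m, dimnames = list(nm, nm))
  pos <- which(denom > 0)
  FC[pos, seq_len(n)] <- sweep(flows[pos, , drop = FALSE], 1L,
                               denom[pos], "/")
  if (include_fleet)
    FC[pos, m] <- landings[pos] / denom[pos]

  q <- DC - t(FC)          # q[a, b]: net direct impact of a on b
  eig <- max(Mod(eigen(q, only.values = TRUE)$values))
  mti <- tryCatch(solve(diag(m) - q) - diag(m), error = function(e)
    stop("(I - q) is singular; spectral radius of q = ",
         signif(eig, 6), call. = FALSE))
  res <- structure(list(mti = mti, q = q, include_fleet = include_fleet,
                        spectral_radius = eig),
                   class = "impact_result")
  ks <- keystone_analysis(res, bal)
  res$epsilon <- ks$epsilon
  res$relative_total_impact <- ks$relative_total_impact
  res$keystoneness <- ks$keystoneness
  res
}

#' Keystoneness and relative total impact
#'
#' The total impact of group i is the root-sum-square of its impacts on
#' the other groups, `epsilon_i = sqrt(sum_{j != i} m_ij^2)`, excluding
#' its self-impact and the fleet column. Relative total impact rescales by
#' the maximum so the most impactful group scores exactly 1. Keystoneness
#' penalises impact by biomass share: `KS_i = log10(epsilon_i (1 - p_i))`
#' with `p_i` the group's share of living biomass (`variant = "biomass"`),
#' so only groups with high impact *despite* low biomass score near or
#' above zero; `variant = "none"` reports `log10(epsilon_i)` unpenalised.
#'
#' @param impact an [mti_matrix()] result.
#' @param bal the corresponding `balanced_web`.
#' @param variant biomass-share penalty (default) or none.
#' @return data frame with `epsilon`, `relative_total_impact`,
#'   `keystoneness` per group (fleet excluded).
#' @export
keystone_analysis <- function(impact, bal,
                              variant = c("biomass", "none")) {
  variant <- match.arg(variant)
  g <- bal$model$groups
  n <- nrow(g)
  mm <- impact$mti[seq_len(n), seq_len(n), drop = FALSE]
  eps <- sqrt(rowSums(mm^2) - diag(mm)^2)
  liv <- g$type != "detritus"
  p <- g$biomass * liv / sum(g$biomass[liv])
  pen <- switch(variant, biomass = 1 - p, none = rep(1, n))
  data.frame(name = g$name, epsilon = eps,
             relative_total_impact = eps / max(eps),
             keystoneness = log10(eps * pen),
             stringsAsFactors = FALSE)
}

#' Pianka niche overlap
#'
#' Symmetric overlap between pairs of groups in resource use. Prey
#' overlap compares diet compositions:
#' `O_jk = sum_i p_ij p_ik / sqrt(sum_i p_ij^2 sum_i p_ik^2)`. Predator
#' overlap applies the same formula to each group's predation-mortality
#' profile (the share of total predation on the group exerted by each
#' predator). Values range from 0 (no shared resource / predator) to 1
#' (identical profiles); groups with an empty profile score 0 against
#' everything, including themselves.
#'
#' @param bal a `balanced_web`.
#' @return object of class `overlap_matrices`: list with `prey_overlap`
#'   and `predator_overlap`, both n x n symmetric.
#' @export
niche_overlap <- function(bal) {
  model <- bal$model
  s <- bal$stats
  g <- model$groups
  cons <- g$type == "consumer"
  consumption <- ifelse(cons, s$consumption, 0)
  flows <- sweep(model$diet, 2L, consumption, "*")
  pred_profile <- matrix(0, nrow(g), nrow(g),
                         dimnames = dimnames(model$diet))
  pos <- s$predation > 0
  pred_profile[pos, ] <- sweep(flows[pos, , drop = FALSE], 1L,
                               s$predation[pos], "/")
  pianka <- function(P) {  # columns = profiles
    nrm <- sqrt(colSums(P^2))
    O <- crossprod(P)
    scale <- outer(nrm, nrm)
    out <- ifelse(scale > 0, O / scale, 0)
    dimnames(out) <- list(colnames(P), colnames(P))
    out
  }
  structure(list(prey_overlap = pianka(model$diet),
                 predator_overlap = pianka(t(pred_profile))),
            class = "overlap_matrices")
}
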