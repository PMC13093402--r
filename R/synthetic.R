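#' Specification for a random synthetic food web
#'
#' Describes the shape of a randomly generated, solvable lake-style food
#' web: a detritus pool, one or more producers, and consumers arranged in
#' trophic layers with sparse, column-stochastic diets biased toward the
#' layer below. Ecotrophic efficiencies are dialled in by construction
#' (see [generate_web()]), so the generated web always solves with every
#' EE inside `ee_target_range`.
#'
#' @param n_consumers number of consumer groups.
#' @param n_producers number of producers (>= 1).
#' @param has_detritus include a detritus pool (default TRUE).
#' @param tl_layers number of consumer layers.
#' @param diet_sparsity probability that an optional diet link is dropped.
#' @param cannibalism_prob probability that a consumer eats itself (a
#'   small diagonal diet entry).
#' @param ee_target_range interval in (0, 1) that every living group's EE
#'   must fall in.
#' @param seed integer seed; the same spec always generates the same web.
#' @return object of class `synthetic_web_spec`.
#' @export
synthetic_web_spec <- function(n_consumers = 8L, n_producers = 1L,
                               has_detritus = TRUE, tl_layers = 3L,
                               diet_sparsity = 0.4,
                               cannibalism_prob = 0.15,
                               ee_target_range = c(0.3, 0.95),
                               seed = 1L) {
  stopifnot(n_consumers >= 1L, n_producers >= 1L,
            tl_layers >= 1L, tl_layers <= n_consumers,
            diet_sparsity >= 0, diet_sparsity <= 1,
            cannibalism_prob >= 0, cannibalism_prob <= 1,
            length(ee_target_range) == 2L,
            ee_target_range[1] > 0, ee_target_range[2] < 1,
            ee_target_range[1] <= ee_target_range[2])
  structure(list(n_consumers = as.integer(n_consumers),
                 n_producers = as.integer(n_producers),
                 has_detritus = isTRUE(has_detritus),
                 tl_layers = as.integer(tl_layers),
                 diet_sparsity = diet_sparsity,
                 cannibalism_prob = cannibalism_prob,
                 ee_target_range = ee_target_range,
                 seed = as.integer(seed)),
            class = "synthetic_web_spec")
}

#' Generate a random solvable food web with known ground truth
#'
#' Builds a web to the given [synthetic_web_spec()]. Consumers are
#' assigned to layers; each consumer's diet is a Dirichlet draw over prey
#' in lower layers (always keeping at least one link to the layer
#' directly below), sparsified at the requested rate, optionally with a
#' small cannibalism loop; columns sum to 1 exactly. Production rates
#' fall with layer (fast plankton-like turnover at the bottom) and
#' consumption rates follow P/Q drawn in [0.05, 0.3], echoing observed
#' lake food webs. Biomasses are then set top-down so that each group's
#' EE equals a target drawn from `ee_target_range`: predators first, each
#' prey's biomass sized to its incoming predation, with landings as the
#' free variable absorbing any slack (biologically: fishing pressure).
#'
#' Every true parameter (biomass, EE, landings) is recorded in the
#' `"truth"` attribute, so solver output can be checked against a known
#' answer after [mask_parameter()] hides one of them.
#'
#' The model is returned with all EE entries `NA` (the solver's usual
#' input state) and all biomasses known.
#'
#' @param spec a [synthetic_web_spec()].
#' @return a validated [food_web_model()] with attribute `truth` (data
#'   frame of true biomass, EE and landings) and `spec`.
#' @export
generate_web <- function(spec) {
  stopifnot(inherits(spec, "synthetic_web_spec"))
  set.seed(spec$seed)
  nc <- spec$n_consumers; np <- spec$n_producers
  nd <- as.integer(spec$has_detritus)
  n <- nc + np + nd
  layer_of <- sort(rep_len(seq_len(spec$tl_layers), nc))  # each layer used
  name <- c(sprintf("Consumer%02d_L%d", seq_len(nc), layer_of),
            sprintf("Producer%02d", seq_len(np)),
            if (nd) "Detritus")
  type <- c(rep("consumer", nc), rep("producer", np),
            if (nd) "detritus")
  base_idx <- nc + seq_len(np + nd)           # producers + detritus
  layer <- c(layer_of, rep(0L, np + nd))

  pb <- numeric(n); qb <- rep(NA_real_, n)
  for (i in seq_len(nc)) {
    pb[i] <- stats::runif(1, c(8, 2, 0.5)[min(layer_of[i], 3L)],
                          c(40, 8, 3)[min(layer_of[i], 3L)])
    qb[i] <- pb[i] / stats::runif(1, 0.05, 0.3)
  }
  pb[nc + seq_len(np)] <- stats::runif(np, 50, 250)
  ee_true <- stats::runif(n, spec$ee_target_range[1],
                          spec$ee_target_range[2])

  diet <- matrix(0, n, n, dimnames = list(name, name))
  for (c_i in seq_len(nc)) {
    below <- which(layer == layer_of[c_i] - 1L)
    if (layer_of[c_i] == 1L) below <- base_idx
    lower <- which(layer < layer_of[c_i] & seq_len(n) != c_i &
                     type != "detritus")
    lower <- setdiff(lower, below)
    keep <- below[stats::runif(length(below)) > spec$diet_sparsity]
    if (length(keep) == 0L) keep <- below[sample.int(length(below), 1L)]
    extra <- lower[stats::runif(length(lower)) > 1 - spec$diet_sparsity / 2]
    prey <- unique(c(keep, extra))
    if (nd && layer_of[c_i] == 1L && !((nc + np + 1L) %in% prey) &&
        stats::runif(1) < 0.5) prey <- c(prey, nc + np + 1L)
    # a bottom-layer consumer never lives on detritus alone
    if (layer_of[c_i] == 1L && !any(prey %in% (nc + seq_len(np))))
      prey <- c(prey, nc + sample.int(np, 1L))
    w <- stats::rgamma(length(prey), shape = 1)
    w <- w / sum(w)
    diet[prey, c_i] <- w
    if (nd) {
      # cap detritivory below the unassimilated fraction so total
      # detritus consumption can never outrun the egestion inflow
      dpool <- nc + np + 1L
      if (diet[dpool, c_i] > 0.15) {
        excess <- diet[dpool, c_i] - 0.15
        rest <- setdiff(which(diet[, c_i] > 0), dpool)
        diet[rest, c_i] <- diet[rest, c_i] +
          excess * diet[rest, c_i] / sum(diet[rest, c_i])
        diet[dpool, c_i] <- 0.15
      }
    }
    if (stats::runif(1) < spec$cannibalism_prob) {
      # keep the self-loop well below production so the web stays solvable
      cap <- 0.5 * (pb[c_i] / qb[c_i]) * spec$ee_target_range[1]
      self <- stats::runif(1, 0.2, 1) * min(0.05, cap)
      diet[, c_i] <- diet[, c_i] * (1 - self)
      diet[c_i, c_i] <- diet[c_i, c_i] + self
    }
  }

  biomass <- numeric(n)
  landings <- numeric(n)
  # top-down: higher layers first, then layer 1, then producers
  order_fill <- c(order(-layer_of), nc + seq_len(np))
  qv <- ifelse(is.na(qb), 0, qb)
  for (i in order_fill) {
    pred_ext <- sum(biomass * qv * diet[i, ], na.rm = TRUE)  # set preds only
    coefficient <- pb[i] * ee_true[i] - qv[i] * diet[i, i]
    if (coefficient <= 0)
      stop("unsatisfiable spec: cannibalism exceeds production for ", name[i])
    if (pred_ext <= 0) {
      biomass[i] <- stats::runif(1, 0.05, 2)
      landings[i] <- ee_true[i] * biomass[i] * pb[i] -
        biomass[i] * qv[i] * diet[i, i]
    } else {
      slack <- if (stats::runif(1) < 0.3) stats::runif(1, 0, 0.3) else 0
      biomass[i] <- pred_ext * (1 + slack) / coefficient
      landings[i] <- ee_true[i] * biomass[i] * pb[i] -
        (pred_ext + biomass[i] * qv[i] * diet[i, i])
    }
  }
  if (nd) { biomass[n] <- 1; ee_true[n] <- NA }
  # zero-slack groups can land at -eps from floating point
  tol <- 1e-9 * pmax(1, abs(ee_true * biomass * pb))
  tol[is.na(tol)] <- 0
  landings[landings < 0 & landings > -tol] <- 0

  groups <- data.frame(name = name, type = type, biomass = biomass,
                       pb = ifelse(type == "detritus", NA, pb),
                       qb = qb, ee = NA_real_, landings = landings,
                       stringsAsFactors = FALSE)
  model <- food_web_model(groups, diet)
  validate_model(model, diet_tol = 1e-9,
                 require_detritus = spec$has_detritus)
  attr(model, "truth") <- data.frame(name = name, biomass = biomass,
                                     ee = ee_true, landings = landings,
                                     stringsAsFactors = FALSE)
  attr(model, "spec") <- spec
  model
}

#' Hide one known parameter of a synthetic web
#'
#' Sets a group's biomass or EE to `NA` (the solver's "unknown" state),
#' filling in the complementary parameter from the recorded ground truth
#' so the system stays solvable. The hidden value remains available in
#' the `truth` attribute for recovery checks; [unmask_parameter()]
#' restores the original model bit for bit.
#'
#' @param model a [generate_web()] model (must carry a `truth` attribute).
#' @param group group name or index.
#' @param which `"biomass"` or `"ee"`.
#' @return the modified model.
#' @export
mask_parameter <- function(model, group, which = c("biomass", "ee")) {
  which <- match.arg(which)
  truth <- attr(model, "truth")
  if (is.null(truth)) stop("model carries no ground-truth ledger")
  i <- if (is.character(group)) match(group, model$groups$name) else group
  if (is.na(i)) stop("unknown group: ", group)
  if (model$groups$type[i] == "detritus" && which == "ee")
    stop("detritus EE is derived, not an input; mask biomass instead")
  masked <- attr(model, "masked")
  prev <- model$groups[i, c("biomass", "ee")]
  if (which == "biomass") {
    model$groups$biomass[i] <- NA
    model$groups$ee[i] <- truth$ee[i]
  } else {
    model$groups$ee[i] <- NA
    model$groups$biomass[i] <- truth$biomass[i]
  }
  attr(model, "truth") <- truth
  attr(model, "masked") <- c(masked, list(list(group = i, which = which,
                                               previous = prev)))
  validate_model(model, diet_tol = 1e-9, require_detritus = FALSE)
  model
}

#' @rdname mask_parameter
#' @export
unmask_parameter <- function(model) {
  masked <- attr(model, "masked")
  if (is.null(masked) || length(masked) == 0L)
    stop("model has no masked parameter")
  last <- masked[[length(masked)]]
  model$groups$biomass[last$group] <- last$previous$biomass
  model$groups$ee[last$group] <- last$previous$ee
  attr(model, "masked") <- if (length(masked) > 1L)
    masked[-length(masked)] else NULL
  model
}
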