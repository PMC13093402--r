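#' Construct a food-web model
#'
#' A `food_web_model` is the unbalanced input object of the package: a table
#' of functional groups plus a diet-composition matrix. Each living group
#' carries biomass `B` (t/km2), a production rate `P/B` (/yr), a consumption
#' rate `Q/B` (/yr, consumers only), an ecotrophic efficiency `EE`
#' (dimensionless), fishery landings (t/km2/yr) and an unassimilated fraction
#' of consumption `GS`. Exactly one of `B`/`EE` may be `NA` per group; the
#' mass-balance solver fills it in.
#'
#' @param groups data frame with columns `name`, `type` (one of
#'   `"consumer"`, `"producer"`, `"detritus"`), `biomass`, `pb`, `qb`, `ee`,
#'   and optionally `landings` (default 0), `unassim` (default 0.2 for
#'   consumers, 0 otherwise), `ba` (biomass accumulation, default 0) and
#'   `migration` (net migration, default 0).
#' @param diet numeric matrix of diet proportions, prey in rows and
#'   predators in columns, in the same order as `groups`. Columns of
#'   non-consumers must be zero.
#' @param import numeric vector: proportion of each predator's diet imported
#'   from outside the system (default all zero).
#' @param area_km2 optional lake surface area, used only when converting
#'   whole-lake tonnes to densities.
#' @return an object of class `food_web_model`.
#' @seealso [validate_model()], [balance_model()], [kaptai_model()]
#' @export
food_web_model <- function(groups, diet, import = NULL, area_km2 = NULL) {
  stopifnot(is.data.frame(groups), is.matrix(diet))
  need <- c("name", "type", "biomass", "pb", "qb", "ee")
  miss <- setdiff(need, names(groups))
  if (length(miss) > 0L)
    stop("groups table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(groups)
  if (!all(dim(diet) == c(n, n)))
    stop("diet matrix must be ", n, " x ", n, " to match the group table")
  groups$name <- as.character(groups$name)
  groups$type <- match.arg(as.character(groups$type),
                           c("consumer", "producer", "detritus"),
                           several.ok = TRUE)
  if (is.null(groups$landings)) groups$landings <- 0
  if (is.null(groups$unassim))
    groups$unassim <- ifelse(groups$type == "consumer", 0.2, 0)
  if (is.null(groups$ba)) groups$ba <- 0
  if (is.null(groups$migration)) groups$migration <- 0
  groups$landings[is.na(groups$landings)] <- 0
  if (is.null(import)) import <- numeric(n)
  import <- as.numeric(unlist(import))
  if (length(import) == 1L) import <- rep(import, n)
  if (length(import) != n)
    stop("import vector must have one entry per group")
  dimnames(diet) <- list(groups$name, groups$name)
  names(import) <- groups$name
  structure(list(groups = groups, diet = diet, import = import,
                 area_km2 = area_km2),
            class = "food_web_model")
}

#' @export
print.food_web_model <- function(x, ...) {
  tab <- table(factor(x$groups$type,
                      c("consumer", "producer", "detritus")))
  cat("food_web_model:", nrow(x$groups), "groups (",
      tab[["consumer"]], "consumers,", tab[["producer"]], "producers,",
      tab[["detritus"]], "detritus )\n")
  nb <- sum(is.na(x$groups$biomass)); ne <- sum(is.na(x$groups$ee))
  cat("  unknowns:", nb, "biomass,", ne, "ecotrophic efficiency\n")
  invisible(x)
}

#' Validate a food-web model
#'
#' Checks the structural invariants required by the solver: per group at
#' most one of `B`/`EE` missing, positive rates for living groups, diet
#' columns of consumers summing to 1 (within `diet_tol`, which defaults to
#' the rounding scale of published diet tables), zero diet columns for
#' producers and detritus, and at least one producer and one detritus pool.
#'
#' @param model a [food_web_model()].
#' @param diet_tol tolerance on consumer diet-column sums (including the
#'   import row). Use `1e-9` for exact machine-built webs; the default
#'   `0.005` accepts print-rounded tables.
#' @param require_detritus demand a detritus pool (the default; webs
#'   without one are legal for the solver but not for detritus-based
#'   indices).
#' @return the model, invisibly, if valid; otherwise an error naming the
#'   offending group or column.
#' @export
validate_model <- function(model, diet_tol = 0.005,
                           require_detritus = TRUE) {
  g <- model$groups
  both <- is.na(g$biomass) & is.na(g$ee)
  if (any(both))
    stop("both biomass and EE missing for group(s): ",
         paste(g$name[both], collapse = ", "))
  living <- g$type != "detritus"
  bad <- living & (is.na(g$pb) | g$pb <= 0)
  if (any(bad))
    stop("P/B must be positive for living group(s): ",
         paste(g$name[bad], collapse = ", "))
  cons <- g$type == "consumer"
  bad <- cons & (is.na(g$qb) | g$qb <= 0)
  if (any(bad))
    stop("Q/B must be positive for consumer(s): ",
         paste(g$name[bad], collapse = ", "))
  if (any(g$landings < 0))
    stop("negative landings for group(s): ",
         paste(g$name[g$landings < 0], collapse = ", "))
  if (any(g$unassim < 0 | g$unassim >= 1))
    stop("unassimilated fraction must be in [0, 1) for: ",
         paste(g$name[g$unassim < 0 | g$unassim >= 1], collapse = ", "))
  if (!any(g$type == "producer")) stop("model needs at least one producer")
  if (require_detritus && !any(g$type == "detritus"))
    stop("model needs a detritus group")
  if (any(model$diet < 0) || any(model$diet > 1))
    stop("diet proportions must lie in [0, 1]")
  csums <- colSums(model$diet) + model$import
  bad <- cons & abs(csums - 1) > diet_tol
  if (any(bad))
    stop("diet column(s) not summing to 1 (tol ", diet_tol, "): ",
         paste(sprintf("%s (%.6f)", g$name[bad], csums[bad]),
               collapse = ", "))
  bad <- !cons & csums > 0
  if (any(bad))
    stop("non-consumer group(s) with nonzero diet column: ",
         paste(g$name[bad], collapse = ", "))
  invisible(model)
}

#' Convert whole-lake catch to areal landings
#'
#' @param catch_tonnes annual catch in tonnes per year.
#' @param area_km2 lake surface area in km2 (> 0).
#' @return landings in t/km2/yr.
#' @export
convert_landings <- function(catch_tonnes, area_km2) {
  if (any(area_km2 <= 0)) stop("area must be positive")
  catch_tonnes / area_km2
}

#' Read a food-web model from disk
#'
#' Two on-disk layouts are supported. `format = "csv"` expects a directory
#' holding `groups.csv` (one row per functional group, landings merged in)
#' and `diet.csv` (prey rows x predator columns, first column the prey
#' names, optional final `Import` row). `format = "json"` / `"yaml"` expect
#' a single document with `groups`, `diet`, `import` and `area_km2` keys as
#' written by [save_model()]. Numeric fields round-trip at full double
#' precision.
#'
#' @param path directory (csv) or file (json/yaml).
#' @param format one of `"csv"`, `"json"`, `"yaml"`; guessed from `path`
#'   when omitted.
#' @param diet_tol passed on to [validate_model()].
#' @return a validated [food_web_model()].
#' @export
load_model <- function(path, format = c("auto", "csv", "json", "yaml"),
                       diet_tol = 0.005) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "csv"
      else if (grepl("\\.ya?ml$", path)) "yaml" else "json"
  }
  if (format == "csv") {
    gf <- file.path(path, "groups.csv"); df <- file.path(path, "diet.csv")
    if (!file.exists(gf)) stop("missing groups.csv under ", path)
    if (!file.exists(df)) stop("missing diet.csv under ", path)
    groups <- utils::read.csv(gf, stringsAsFactors = FALSE)
    dd <- utils::read.csv(df, stringsAsFactors = FALSE, check.names = FALSE)
    prey <- dd[[1L]]
    mat <- as.matrix(dd[, -1L, drop = FALSE])
    imp <- numeric(nrow(groups))
    if (any(tolower(prey) == "import")) {
      k <- which(tolower(prey) == "import")
      row <- mat[k, ]
      mat <- mat[-k, , drop = FALSE]; prey <- prey[-k]
      imp[match(colnames(mat), groups$name)] <- row
    }
    if (!identical(prey, groups$name))
      stop("diet.csv prey rows do not match groups.csv order")
    diet <- matrix(0, nrow(groups), nrow(groups),
                   dimnames = list(groups$name, groups$name))
    diet[, colnames(mat)] <- mat
    area <- attr(groups, "area_km2")
    model <- food_web_model(groups, diet, imp, area)
  } else {
    doc <- if (format == "json") jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    diet <- matrix(unlist(doc$diet), nrow = length(doc$groups$name))
    model <- food_web_model(as.data.frame(doc$groups), diet,
                            doc$import, doc$area_km2)
  }
  validate_model(model, diet_tol = diet_tol)
  model
}

#' Write a food-web model to disk
#'
#' @param model a [food_web_model()].
#' @param path directory (csv) or file (json/yaml).
#' @param format one of `"csv"`, `"json"`, `"yaml"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("csv", "json", "yaml")) {
  format <- match.arg(format)
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(model$groups, file.path(path, "groups.csv"),
                     row.names = FALSE)
    dd <- data.frame(prey = c(rownames(model$diet), "Import"),
                     rbind(model$diet, model$import),
                     check.names = FALSE)
    utils::write.csv(dd, file.path(path, "diet.csv"), row.names = FALSE)
  } else {
    doc <- list(groups = model$groups,
                diet = apply(model$diet, 2L, identity, simplify = FALSE),
                import = as.list(model$import),
                area_km2 = model$area_km2)
    if (format == "json")
      jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE)
    else
      yaml::write_yaml(doc, path, precision = 15L)
  }
  invisible(path)
}

# shared helpers ------------------------------------------------------------

consumer_idx <- function(model) which(model$groups$type == "consumer")
producer_idx <- function(model) which(model$groups$type == "producer")
detritus_idx <- function(model) which(model$groups$type == "detritus")
living_idx   <- function(model) which(model$groups$type != "detritus")
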