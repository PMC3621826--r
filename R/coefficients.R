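#' The 12-analyte MBDA panel
#'
#' Eleven serum proteins feed the component models (predicted TJC28, SJC28
#' and patient global assessment); CRP enters the combination equation
#' directly. CRP concentrations are in mg/L, all other analytes in pg/mL.
#'
#' @return Character vector of the 12 panel analyte identifiers.
#' @export
mbda_panel <- function() {
  c("TNFRI", "IL6", "VCAM1", "EGF", "VEGFA", "YKL40",
    "MMP1", "MMP3", "SAA", "leptin", "resistin", "CRP")
}

#' Analytes available to the component sub-models
#'
#' @return The panel minus CRP (CRP is never a component-model predictor).
#' @export
mbda_component_analytes <- function() {
  setdiff(mbda_panel(), "CRP")
}

#' Construct an algorithm coefficient set
#'
#' Bundles every constant of the scoring pipeline as configuration: the
#' per-component linear models (on power-transformed concentrations), the
#' 2x2 Curds-and-Whey shrinkage matrix over the joint-count predictions, the
#' DAS28-CRP-analogous combination weights, and the scaling of the combined
#' value onto the integer 1-100 score.
#'
#' @param components Named list with elements `ptjc28`, `psjc28`, `ppga`,
#'   each a list with `intercept` (scalar) and `coefficients` (named numeric
#'   vector over panel analytes, CRP excluded).
#' @param shrinkage 2x2 numeric shrinkage matrix applied to
#'   `c(ptjc28, psjc28)`; rows/cols ordered (tjc, sjc).
#' @param combination Named numeric vector with weights `sqrt_iptjc`,
#'   `sqrt_isjc`, `log_crp`, `ppga` and `constant`. `ppga` weighs the
#'   predicted patient global assessment on its 0-10 scale.
#' @param scale,offset Final linear map: `score = round(pre_scale * scale +
#'   offset)` clamped to `bounds`. Defaults 10.53 and 1.
#' @param bounds Integer score bounds, default `c(1, 100)`.
#' @param exponent Power transform applied to marker concentrations before
#'   the component models, default 0.1.
#' @param crp_unit Unit the combination's log-CRP term expects ("mg/L").
#' @param metadata Optional list (training provenance etc.).
#' @return An object of class `mbda_coefficients`.
#' @export
algorithm_coefficients <- function(components, shrinkage, combination,
                                   scale = 10.53, offset = 1,
                                   bounds = c(1L, 100L), exponent = 0.1,
                                   crp_unit = "mg/L", metadata = list()) {
  stopifnot(is.list(components), is.numeric(scale), is.numeric(offset))
  needed <- c("ptjc28", "psjc28", "ppga")
  missing_cmp <- setdiff(needed, names(components))
  if (length(missing_cmp)) {
    stop("missing component model(s): ", paste(missing_cmp, collapse = ", "))
  }
  if (scale <= 0) stop("scale factor must be > 0")
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("bounds must be (low, high) with low < high")
  }
  allowed <- mbda_component_analytes()
  for (cmp in needed) {
    m <- components[[cmp]]
    if (is.null(m$intercept) || is.null(m$coefficients)) {
      stop("component model '", cmp, "' needs intercept and coefficients")
    }
    m$coefficients <- unlist(m$coefficients)
    bad <- setdiff(names(m$coefficients), allowed)
    if (length(bad)) {
      stop("unknown analyte(s) in component '", cmp, "': ",
           paste(bad, collapse = ", "))
    }
    components[[cmp]] <- list(intercept = as.numeric(m$intercept),
                              coefficients = m$coefficients)
  }
  shrinkage <- matrix(as.numeric(unlist(shrinkage)), 2, 2,
                      dimnames = list(c("tjc", "sjc"), c("tjc", "sjc")))
  if (any(!is.finite(shrinkage))) stop("shrinkage matrix must be finite")
  combination <- unlist(combination)
  wn <- c("sqrt_iptjc", "sqrt_isjc", "log_crp", "ppga", "constant")
  if (!all(wn %in% names(combination))) {
    stop("combination weights must name: ", paste(wn, collapse = ", "))
  }
  structure(
    list(components = components[needed],
         shrinkage = shrinkage,
         combination = combination[wn],
         scale = scale, offset = offset,
         bounds = as.integer(bounds), exponent = exponent,
         crp_unit = crp_unit, metadata = metadata),
    class = "mbda_coefficients"
  )
}

#' @export
print.mbda_coefficients <- function(x, ...) {
  cat("MBDA algorithm coefficients\n")
  for (cmp in names(x$components)) {
    cf <- x$components[[cmp]]$coefficients
    cat(sprintf("  %s: intercept %.4g + %d analyte(s): %s\n", cmp,
                x$components[[cmp]]$intercept, length(cf),
                paste(names(cf), collapse = ", ")))
  }
  cat(sprintf("  shrinkage: [%.4g %.4g; %.4g %.4g]\n",
              x$shrinkage[1, 1], x$shrinkage[1, 2],
              x$shrinkage[2, 1], x$shrinkage[2, 2]))
  cat(sprintf("  combination: %s\n",
              paste(sprintf("%s=%.4g", names(x$combination), x$combination),
                    collapse = ", ")))
  cat(sprintf("  score = clamp(round(pre_scale * %.4g + %.4g), %d, %d); exponent %.3g\n",
              x$scale, x$offset, x$bounds[1], x$bounds[2], x$exponent))
  invisible(x)
}

#' Load algorithm coefficients from a JSON config
#'
#' Defaults are applied for `scale` (10.53), `offset` (1), `bounds`
#' (1, 100) and `exponent` (0.1) when the file omits them. Unknown analytes
#' or a missing component model raise an error.
#'
#' @param path Path to a JSON file.
#' @return An `mbda_coefficients` object.
#' @export
load_coefficients <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$components)) stop("config lacks 'components'")
  components <- lapply(cfg$components, function(m) {
    list(intercept = m$intercept, coefficients = unlist(m$coefficients))
  })
  if (is.null(cfg$shrinkage)) stop("config lacks 'shrinkage'")
  algorithm_coefficients(
    components = components,
    shrinkage = cfg$shrinkage,
    combination = unlist(cfg$combination),
    scale = if (is.null(cfg$scale)) 10.53 else cfg$scale,
    offset = if (is.null(cfg$offset)) 1 else cfg$offset,
    bounds = if (is.null(cfg$bounds)) c(1L, 100L) else cfg$bounds,
    exponent = if (is.null(cfg$exponent)) 0.1 else cfg$exponent,
    crp_unit = if (is.null(cfg$crp_unit)) "mg/L" else cfg$crp_unit,
    metadata = if (is.null(cfg$metadata)) list() else as.list(cfg$metadata)
  )
}

#' Write algorithm coefficients to JSON
#'
#' @param coeffs An `mbda_coefficients` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "mbda_coefficients"))
  cfg <- list(
    components = lapply(coeffs$components, function(m) {
      list(intercept = m$intercept, coefficients = as.list(m$coefficients))
    }),
    shrinkage = unclass(coeffs$shrinkage),
    combination = as.list(coeffs$combination),
    scale = coeffs$scale, offset = coeffs$offset,
    bounds = coeffs$bounds, exponent = coeffs$exponent,
    crp_unit = coeffs$crp_unit, metadata = coeffs$metadata
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The shipped default coefficient set
#'
#' The component sub-models and shrinkage matrix in the shipped config are
#' SYNTHETIC: they were produced by this package's own CW-LASSO trainer on
#' the "training-like" synthetic cohort, because the printed source
#' equations are available only as display images and could not be
#' transcribed. The combination weights are the DAS28-CRP(4) weights and
#' the scaling constants (10.53, offset 1, bounds 1-100, exponent 0.1) are
#' the published ones.
#'
#' @return An `mbda_coefficients` object.
#' @export
default_coefficients <- function() {
  path <- system.file("extdata", "coefficients_default_synthetic.json",
                      package = "mbda", mustWork = TRUE)
  load_coefficients(path)
}
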