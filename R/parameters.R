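# ParameterSet: a named numeric vector over the full registry of kinetic
# constants, with a role ("reference" or "estimated") and unit annotations.

.param_unit <- function(key) {
  if (key == "ADK.k") return("1/(mM.s)")
  if (key == "ATPase.k") return("mM/s")
  suf <- sub("^[^.]+\\.", "", key)
  if (suf == "Vmax") return("mM/s")
  if (grepl("^(Km|Ki|Ka|K05|Kia|Ksat)", suf)) return("mM")
  if (suf %in% c("GLCec_min", "Pi_ref")) return("mM")
  if (suf == "k") return("1/s")
  "1"
}

#' Construct a parameter set
#'
#' @param values named numeric vector or list; names must be a subset of
#'   [model_parameters()]. Missing constants are an error unless `base` is
#'   given, in which case `values` overrides `base`.
#' @param role `"reference"` or `"estimated"`; the regularization penalty is
#'   computed against a reference-role set.
#' @param base optional parameter set supplying defaults
#' @return an object of class `parameter_set` (named numeric vector)
#' @export
parameter_set <- function(values = NULL, role = c("estimated", "reference"),
                          base = NULL) {
  role <- match.arg(role)
  keys <- model_parameters()
  out <- setNames(rep(NA_real_, length(keys)), keys)
  if (!is.null(base)) {
    stopifnot(inherits(base, "parameter_set"))
    out[] <- as.numeric(base)[match(keys, names(base))]
  }
  if (!is.null(values)) {
    values <- unlist(values)
    unknown <- setdiff(names(values), keys)
    if (length(unknown))
      stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
    out[names(values)] <- as.numeric(values)
  }
  structure(out, class = "parameter_set", role = role)
}

#' Validate a parameter set
#'
#' Checks completeness and the positivity invariants: every constant must be
#' strictly positive, except `HXT.GLCec_min` (>= 0) and the `HXT.sensing`
#' flag (0 or 1).
#' @param p a `parameter_set`
#' @return `p`, invisibly; errors on violation
#' @export
validate_parameter_set <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  keys <- model_parameters()
  if (!identical(names(p), keys)) stop("parameter set keys out of order")
  if (anyNA(p)) stop("missing values for: ",
                     paste(keys[is.na(p)], collapse = ", "))
  relaxed <- c("HXT.GLCec_min", "HXT.sensing")
  strict <- setdiff(keys, relaxed)
  bad <- strict[as.numeric(p[strict]) <= 0]
  if (length(bad)) stop("non-positive constant(s): ", paste(bad, collapse = ", "))
  if (p[["HXT.GLCec_min"]] < 0) stop("HXT.GLCec_min must be >= 0")
  if (!p[["HXT.sensing"]] %in% c(0, 1)) stop("HXT.sensing must be 0 or 1")
  invisible(p)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set role=%s, %d constants>\n",
              attr(x, "role"), length(x)))
  invisible(x)
}

#' Role of a parameter set ("reference" or "estimated")
#' @param p a `parameter_set`
#' @export
parameter_role <- function(p) attr(p, "role")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "feastfamine")
  if (!nzchar(path)) stop("missing packaged file ", file)
  path
}

#' Shipped parameter sets
#'
#' `calibrated_parameters()` is the set fitted to the feast/famine regime
#' (hexose transport and phosphorylation constants at their adapted values,
#' glucose sensing on). `reference_parameters()` carries the pre-adaptation
#' (chemostat-fitted) values for HXT, HXK/GLK, NTH1 affinity and maintenance
#' ATPase; all other constants are shared.
#' @return a `parameter_set`
#' @rdname shipped-parameters
#' @export
calibrated_parameters <- function() {
  read_parameterset(.extdata("params_calibrated.json"))
}

#' @rdname shipped-parameters
#' @export
reference_parameters <- function() {
  read_parameterset(.extdata("params_reference.json"))
}

#' Read a parameter set from a flat key/value JSON file
#'
#' The file carries `role`, `values` (flat "REACTION.constant" map) and
#' optional `units`. Unknown keys and schema violations are rejected.
#' @param path file path
#' @return a `parameter_set`
#' @export
read_parameterset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$values))
    stop("parameter file ", path, " lacks a 'values' map")
  role <- if (identical(obj$role, "reference")) "reference" else "estimated"
  p <- parameter_set(obj$values, role = role)
  validate_parameter_set(p)
  p
}

#' Write a parameter set to JSON (round-trip stable)
#' @param p a `parameter_set`
#' @param path output file
#' @param description optional free-text description stored in the file
#' @export
write_parameterset <- function(p, path, description = NULL) {
  validate_parameter_set(p)
  units <- vapply(names(p), .param_unit, "")
  obj <- list(role = parameter_role(p),
              description = description %||% "kinetic constants",
              values = as.list(setNames(as.numeric(p), names(p))),
              units = as.list(units))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold-change report between a reference and an estimated parameter set
#'
#' Fold change is estimated/reference, rounded to `digits` decimals.
#' Constants whose relative change is below `threshold` are omitted by
#' default, mirroring how adaptation tables report only the constants that
#' moved.
#' @param reference,estimated `parameter_set` objects
#' @param threshold relative-change cutoff for inclusion (default 5%)
#' @param digits decimals for the reported fold change
#' @param all include unchanged parameters too
#' @return data.frame with enzyme, parameter, reference, estimated, fold_change
#' @export
fold_change_report <- function(reference, estimated, threshold = 0.05,
                               digits = 2, all = FALSE) {
  keys <- intersect(names(reference), names(estimated))
  missing_keys <- setdiff(union(names(reference), names(estimated)), keys)
  ref <- as.numeric(reference[keys])
  est <- as.numeric(estimated[keys])
  fc <- est / ref
  rel <- abs(fc - 1)
  keep <- if (all) rep(TRUE, length(keys)) else rel >= threshold
  out <- data.frame(
    enzyme = sub("\\..*$", "", keys[keep]),
    parameter = sub("^[^.]+\\.", "", keys[keep]),
    reference = ref[keep],
    estimated = est[keep],
    fold_change = round(fc[keep], digits),
    stringsAsFactors = FALSE
  )
  attr(out, "missing") <- missing_keys
  out[order(out$enzyme, out$parameter), , drop = FALSE]
}
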