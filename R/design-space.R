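#' Define a single optimization variable
#'
#' A variable is described in physical units by its name, unit string, bounds
#' and role in the reactor model. Roles tell the simulator how to interpret a
#' condition vector (e.g. which entry is the bed temperature and which is the
#' liquid flow rate).
#'
#' @param name Variable identifier (unique within a design space).
#' @param unit Unit string, e.g. `"degC"`, `"mL/min"`, `"mol/L"`, `"min"`,
#'   `"ratio"`.
#' @param lower,upper Numeric bounds in physical units; `lower < upper`.
#' @param role One of `"temperature"`, `"liquid_flow"`, `"flow_ratio"`,
#'   `"concentration"`, `"residence_time"`, `"equivalents"`.
#' @return An object of class `flowbo_variable`.
#' @export
variable_spec <- function(name, unit, lower, upper,
                          role = c("temperature", "liquid_flow", "flow_ratio",
                                   "concentration", "residence_time",
                                   "equivalents")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(lower) || !is.numeric(upper) || !(lower < upper)) {
    stop("variable '", name, "': lower bound must be strictly below upper bound",
         call. = FALSE)
  }
  structure(
    list(name = name, unit = unit, lower = as.numeric(lower),
         upper = as.numeric(upper), role = role),
    class = "flowbo_variable"
  )
}

#' Assemble a design space from variable specs
#'
#' @param ... `flowbo_variable` objects, in the order used by condition
#'   vectors.
#' @return An object of class `flowbo_space` with elements `variables`
#'   (named list) and `n`.
#' @export
design_space <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1]]) &&
      !inherits(vars[[1]], "flowbo_variable")) {
    vars <- vars[[1]]
  }
  stopifnot(length(vars) >= 1L,
            all(vapply(vars, inherits, logical(1), "flowbo_variable")))
  nms <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("variable names must be unique", call. = FALSE)
  names(vars) <- nms
  structure(list(variables = vars, n = length(vars)), class = "flowbo_space")
}

#' @export
print.flowbo_space <- function(x, ...) {
  cat("Design space with", x$n, "variables:\n")
  for (v in x$variables) {
    cat(sprintf("  %-12s [%g, %g] %s (%s)\n",
                v$name, v$lower, v$upper, v$unit, v$role))
  }
  invisible(x)
}

#' Shipped design-space presets
#'
#' Four presets cover the campaign modes: `"step1"` (packed-bed hydrogenation:
#' bed temperature, liquid flow, feed concentration), `"step2"` and
#' `"step2-im"` (amidation: coil temperature, residence time, anhydride
#' equivalents; the `-im` variant is identical and exists to label campaigns
#' run on the intermediate-mixture feed), and `"telescoped"` (both reactors:
#' two temperatures, substrate-pump flow, substrate-to-anhydride flow-rate
#' ratio). Numeric bounds are package defaults chosen to be consistent with
#' the reactor model; override them by constructing a space with
#' [variable_spec()] or via a config file.
#'
#' @param name Preset name.
#' @return A `flowbo_space`.
#' @export
design_space_preset <- function(name = c("step1", "step2", "step2-im",
                                         "telescoped")) {
  name <- match.arg(name)
  switch(name,
    step1 = design_space(
      variable_spec("T1", "degC", 60, 150, "temperature"),
      variable_spec("Q1", "mL/min", 0.1, 1.0, "liquid_flow"),
      variable_spec("C1", "mol/L", 0.025, 0.10, "concentration")
    ),
    step2 = ,
    `step2-im` = design_space(
      variable_spec("T2", "degC", 30, 100, "temperature"),
      variable_spec("tau2", "min", 0.5, 5.0, "residence_time"),
      variable_spec("equiv3", "ratio", 1.0, 3.0, "equivalents")
    ),
    telescoped = design_space(
      variable_spec("T1", "degC", 60, 150, "temperature"),
      variable_spec("T2", "degC", 30, 100, "temperature"),
      variable_spec("Q1", "mL/min", 0.1, 1.0, "liquid_flow"),
      variable_spec("ratio", "ratio", 2, 10, "flow_ratio")
    )
  )
}

#' Load a design space from a plain-text config
#'
#' Reads a YAML preset file (one block per preset, each with a `variables`
#' list of name/unit/lower/upper/role entries) and builds the named design
#' space. With no `path`, the presets shipped with the package are used;
#' these match [design_space_preset()].
#'
#' @param name Preset name within the file.
#' @param path Optional path to a YAML preset file.
#' @return A `flowbo_space`.
#' @export
read_design_space <- function(name, path = NULL) {
  path <- path %||% system.file("extdata", "presets", "design_spaces.yaml",
                                package = "flowbo", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (!name %in% names(cfg)) {
    stop("no design-space preset '", name, "' in ", path, call. = FALSE)
  }
  vars <- lapply(cfg[[name]]$variables, function(v) {
    variable_spec(v$name, v$unit, v$lower, v$upper, v$role)
  })
  design_space(vars)
}

space_lower <- function(space) {
  vapply(space$variables, `[[`, numeric(1), "lower")
}

space_upper <- function(space) {
  vapply(space$variables, `[[`, numeric(1), "upper")
}

check_in_bounds <- function(space, x, tol = 1e-9) {
  lo <- space_lower(space); up <- space_upper(space)
  bad <- which(x < lo - tol * (up - lo) | x > up + tol * (up - lo))
  if (length(bad)) {
    stop("condition out of bounds for variable(s): ",
         paste(names(space$variables)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Map conditions to and from the unit hypercube
#'
#' `to_unit()` affinely rescales a condition vector (or matrix, one row per
#' condition) so each variable's bounds map to `[0, 1]`; `from_unit()` is the
#' inverse. All surrogate modelling and acquisition optimization happen in
#' unit-scaled coordinates.
#'
#' @param space A `flowbo_space`.
#' @param x Numeric vector of length `space$n`, or a matrix with `space$n`
#'   columns (physical units for `to_unit`, unit-scaled for `from_unit`).
#' @return Vector or matrix of the same shape.
#' @export
to_unit <- function(space, x) {
  lo <- space_lower(space); up <- space_upper(space)
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x))) check_in_bounds(space, x[i, ])
    sweep(sweep(x, 2, lo, "-"), 2, up - lo, "/")
  } else {
    check_in_bounds(space, x)
    stats::setNames((x - lo) / (up - lo), names(space$variables))
  }
}

#' @rdname to_unit
#' @export
from_unit <- function(space, x) {
  lo <- space_lower(space); up <- space_upper(space)
  if (is.matrix(x)) {
    out <- sweep(sweep(x, 2, up - lo, "*"), 2, lo, "+")
    colnames(out) <- names(space$variables)
    out
  } else {
    stats::setNames(lo + x * (up - lo), names(space$variables))
  }
}

#' Latin hypercube initialization design
#'
#' Generates the `2n + 1` space-filling initial conditions used to seed a
#' campaign, where `n` is the number of optimization variables: 7 points for
#' the three-variable single-step spaces, 9 for the four-variable telescoped
#' space. The design is a seeded random-permutation Latin hypercube (one point
#' per equal-width stratum per dimension, position jittered within each
#' stratum); no space-filling optimization is applied.
#'
#' @param space A `flowbo_space`.
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @param n_points Number of points; defaults to `2 * space$n + 1`.
#' @return Matrix of conditions in physical units, `n_points` rows, one
#'   column per variable.
#' @export
lhs_design <- function(space, seed, n_points = 2L * space$n + 1L) {
  stopifnot(n_points >= 1L)
  u <- with_seed(seed, lhs::randomLHS(n_points, space$n))
  from_unit(space, u)
}

# Evaluate an expression under a temporary RNG state.  All package
# randomness funnels through here so campaigns are reproducible and never
# disturb the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed and a stream label; keeps
# independent reproducible streams per campaign / per measurement.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
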