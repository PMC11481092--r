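#' Mass-flow breakdown of a process at steady state
#'
#' One row per input material (name, mass rate in g/h, solvent flag) plus
#' the product mass rate. The basis for all green metrics.
#'
#' @param materials Data frame with columns `material`, `rate` (g/h) and
#'   `solvent` (logical).
#' @param product_rate Product mass rate, g/h.
#' @return An object of class `flowbo_massflow` with derived `total_rate`
#'   and `solvent_fraction`.
#' @export
mass_flow_breakdown <- function(materials, product_rate) {
  stopifnot(is.data.frame(materials),
            all(c("material", "rate", "solvent") %in% names(materials)),
            all(materials$rate >= 0), product_rate >= 0)
  total <- sum(materials$rate)
  structure(list(
    materials = materials,
    product_rate = product_rate,
    total_rate = total,
    solvent_rate = sum(materials$rate[materials$solvent]),
    solvent_fraction = if (total > 0)
      sum(materials$rate[materials$solvent]) / total else 0,
    flagged = product_rate <= 0
  ), class = "flowbo_massflow")
}

#' Breakdown from printed process totals
#'
#' Reconstructs a two-material breakdown (solvent and everything else) from
#' the totals a process report prints: total mass rate, product mass rate,
#' and the percentage of the total mass that is solvent. Useful for desk
#' re-analysis of published numbers.
#'
#' @param total_rate Total input mass rate, g/h.
#' @param product_rate Product mass rate, g/h.
#' @param solvent_pct Percentage of total mass that is solvent.
#' @return A `flowbo_massflow`.
#' @export
breakdown_from_totals <- function(total_rate, product_rate, solvent_pct) {
  solv <- total_rate * solvent_pct / 100
  mass_flow_breakdown(
    data.frame(material = c("solvent", "non-solvent"),
               rate = c(solv, total_rate - solv),
               solvent = c(TRUE, FALSE)),
    product_rate = product_rate)
}

#' Mass flows of a rig configuration at given optimum conditions
#'
#' Converts steady-state rig state into a [mass_flow_breakdown()]: solvent
#' mass is the liquid feed mass (flow times solvent density) minus the mass
#' of dissolved solutes, solute rates follow from stock concentrations,
#' molar masses and flows, hydrogen from the preset's gas feed, and the
#' product rate from the outlet concentration.
#'
#' @param mode `"step1"`, `"step2"` or `"telescoped"`.
#' @param cond Optimum conditions (named, physical units).
#' @param preset A `flowbo_rig`.
#' @param outlet Outlet `flowbo_stream` of the final reactor at `cond`.
#' @param feed Feed stream (step-2 mode; supplies the reservoir composition).
#' @return A `flowbo_massflow`.
#' @export
mass_flows <- function(mode, cond, preset, outlet, feed = NULL) {
  g_per_h <- function(conc, M, flow_ml_min) conc * M * flow_ml_min * 60 / 1000
  rho60 <- function(flow) flow * preset$solvent_density * 60

  rows <- switch(mode,
    step1 = {
      Q1 <- cond[["Q1"]]
      C1 <- if ("C1" %in% names(cond)) cond[["C1"]] else preset$stock_conc_1
      solute1 <- g_per_h(C1, MOLAR_MASS[["c1"]], Q1)
      data.frame(
        material = c("2-MeTHF", "4-nitrophenol", "hydrogen"),
        rate = c(rho60(Q1) - solute1, solute1, preset$gas_mass_rate),
        solvent = c(TRUE, FALSE, FALSE))
    },
    step2 = {
      stopifnot(!is.null(feed))
      Q2 <- preset$V_R2 / cond[["tau2"]]
      solutes <- c(
        g_per_h(feed$conc[["c1"]], MOLAR_MASS[["c1"]], Q2),
        g_per_h(feed$conc[["c2"]], MOLAR_MASS[["c2"]], Q2),
        g_per_h(cond[["equiv3"]] * feed$conc[["c2"]], MOLAR_MASS[["c3"]], Q2))
      data.frame(
        material = c("2-MeTHF", "4-nitrophenol", "4-aminophenol",
                     "acetic anhydride"),
        rate = c(rho60(Q2) - sum(solutes), solutes),
        solvent = c(TRUE, FALSE, FALSE, FALSE))
    },
    telescoped = {
      Q1 <- cond[["Q1"]]
      Q3 <- Q1 / cond[["ratio"]]
      solute1 <- g_per_h(preset$stock_conc_1, MOLAR_MASS[["c1"]], Q1)
      solute3 <- g_per_h(preset$stock_conc_3, MOLAR_MASS[["c3"]], Q3)
      data.frame(
        material = c("2-MeTHF", "4-nitrophenol", "acetic anhydride",
                     "hydrogen"),
        rate = c(rho60(Q1) + rho60(Q3) - solute1 - solute3,
                 solute1, solute3, preset$gas_mass_rate),
        solvent = c(TRUE, FALSE, FALSE, FALSE))
    },
    stop("unknown mode: ", mode, call. = FALSE)
  )
  product_species <- if (mode == "step1") "c2" else "c4"
  product <- g_per_h(outlet$conc[[product_species]],
                     MOLAR_MASS[[product_species]], outlet$liquid_flow)
  mass_flow_breakdown(rows, product)
}

#' Process mass intensity
#'
#' Total input mass per mass of product; 1 is ideal (every gram fed ends up
#' in the product). Computed on steady-state rates, which is equivalent to
#' the mass-ratio definition.
#'
#' @param bd A `flowbo_massflow`.
#' @return Dimensionless PMI.
#' @export
pmi <- function(bd) {
  if (bd$product_rate <= 0) {
    stop("PMI undefined: product mass rate is zero", call. = FALSE)
  }
  bd$total_rate / bd$product_rate
}

#' PMI under a solvent-recycling scenario
#'
#' Counts only `retained_fraction` of the solvent mass as consumed (the rest
#' assumed recycled between runs); the default 0.2 is the best-case 20%
#' scenario.
#'
#' @param bd A `flowbo_massflow`.
#' @param retained_fraction Fraction of solvent mass counted.
#' @return Dimensionless PMI.
#' @export
pmi_solvent_scenario <- function(bd, retained_fraction = 0.2) {
  if (bd$product_rate <= 0) {
    stop("PMI undefined: product mass rate is zero", call. = FALSE)
  }
  nonsolv <- bd$total_rate - bd$solvent_rate
  (nonsolv + retained_fraction * bd$solvent_rate) / bd$product_rate
}

#' Product produced over an operating period
#'
#' @param bd A `flowbo_massflow`.
#' @param hours Operating time, h.
#' @return Grams of product.
#' @export
throughput <- function(bd, hours) {
  stopifnot(hours >= 0)
  bd$product_rate * hours
}

#' Comparison table across optimization modes
#'
#' One row per mode (OSAT step 1, OSAT step 2, OSAT combined, telescoped)
#' with the total and product mass rates, the 20%-solvent PMI, the solvent
#' percentage and the number of experiments needed to reach the optimum.
#' The OSAT-combined experiment count is the sum of the two single-step
#' campaigns; its mass flows describe the two steps chained at their
#' separately found optima.
#'
#' @param entries Named list; each element is a list with `breakdown` (a
#'   `flowbo_massflow`) and `experiments` (count). Expected names:
#'   `"osat_step1"`, `"osat_step2"`, `"osat_combined"`, `"telescoped"`;
#'   missing modes are omitted with a warning.
#' @param retained_fraction Solvent fraction counted in the PMI scenario.
#' @return Data frame in report column order.
#' @export
comparison_report <- function(entries, retained_fraction = 0.2) {
  modes <- c("osat_step1", "osat_step2", "osat_combined", "telescoped")
  missing <- setdiff(modes, names(entries))
  if (length(missing)) {
    warning("comparison report missing mode(s): ",
            paste(missing, collapse = ", "))
  }
  present <- intersect(modes, names(entries))
  rows <- lapply(present, function(m) {
    e <- entries[[m]]
    data.frame(
      mode = m,
      total_mass_g_h = e$breakdown$total_rate,
      product_mass_g_h = e$breakdown$product_rate,
      pmi_20pct_solvent = pmi_solvent_scenario(e$breakdown,
                                               retained_fraction),
      solvent_pct = 100 * e$breakdown$solvent_fraction,
      experiments_to_optimum = e$experiments)
  })
  do.call(rbind, rows)
}

#' Published comparison-table breakdowns
#'
#' The four process rows of the published comparison (total mass rate,
#' product mass rate, solvent percentage, experiments to optimum) as
#' [breakdown_from_totals()] objects, for desk re-analysis.
#'
#' @return Named list of entries suitable for [comparison_report()].
#' @export
published_table_entries <- function() {
  list(
    osat_step1 = list(breakdown = breakdown_from_totals(26.9, 0.021, 96),
                      experiments = 9L),
    osat_step2 = list(breakdown = breakdown_from_totals(21.6, 0.072, 99),
                      experiments = 11L),
    osat_combined = list(breakdown = breakdown_from_totals(39.9, 0.044, 97),
                         experiments = 20L),
    telescoped = list(breakdown = breakdown_from_totals(44.8, 0.190, 95),
                      experiments = 12L)
  )
}
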