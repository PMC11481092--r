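#' Default study configuration
#'
#' The full description of a reproducible study: which presets to use, the
#' measurement-noise model, campaign budgets, output directory and the
#' global seed from which every campaign's random stream is derived.
#'
#' @return Named list of defaults (a valid config).
#' @export
default_study_config <- function() {
  list(
    kinetics = "paper",
    rig_osat = "osat",
    rig_telescoped = "telescoped",
    noise = list(sigma_abs = 0.01, p_fault = 0.02),
    campaign = list(
      budget_osat = 25L, budget_telescoped = 18L,
      monitoring_interval = 4L, plateau_window = 5L, plateau_delta = 0.005,
      hours_per_experiment = 2),
    out_dir = NULL,
    seed = 1L
  )
}

# Order-insensitive FNV-1a style hash of a config, for output provenance.
# The output directory is not part of the study's identity.
config_hash <- function(config) {
  config$out_dir <- NULL
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Validate and normalize a study configuration
#'
#' Checks every key against the schema of [default_study_config()], fills
#' defaults for missing keys, and aggregates all problems into one
#' human-readable error. Unknown keys are rejected with their location.
#'
#' @param config Named list (e.g. from [read_study_config()]).
#' @return The normalized config (input plus defaults).
#' @export
validate_config <- function(config) {
  defaults <- default_study_config()
  errors <- character(0)
  if (!is.list(config)) {
    stop("config must be a named list; required keys: ",
         paste(names(defaults), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  merged <- utils::modifyList(defaults, config[intersect(names(config),
                                                         names(defaults))])
  for (nested in c("noise", "campaign")) {
    bad <- setdiff(names(merged[[nested]]), names(defaults[[nested]]))
    if (length(bad)) {
      errors <- c(errors, paste0("unknown key(s) under '", nested, "': ",
                                 paste(bad, collapse = ", ")))
    }
    merged[[nested]] <- utils::modifyList(defaults[[nested]],
                                          merged[[nested]])
  }
  if (!merged$kinetics %in% "paper") {
    errors <- c(errors, paste0("unknown kinetics preset: ", merged$kinetics))
  }
  for (k in c("rig_osat", "rig_telescoped")) {
    if (!merged[[k]] %in% c("osat", "telescoped")) {
      errors <- c(errors, paste0("unknown rig preset under '", k, "': ",
                                 merged[[k]]))
    }
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(merged$noise$sigma_abs >= 0, "noise$sigma_abs must be >= 0")
  chk(merged$noise$p_fault >= 0 && merged$noise$p_fault < 1,
      "noise$p_fault must be in [0, 1)")
  chk(merged$campaign$budget_osat >= 7, "campaign$budget_osat must cover LHS")
  chk(merged$campaign$budget_telescoped >= 9,
      "campaign$budget_telescoped must cover LHS")
  chk(merged$campaign$monitoring_interval >= 2,
      "campaign$monitoring_interval must be >= 2")
  chk(is.numeric(merged$seed) && length(merged$seed) == 1,
      "seed must be a single integer")
  if (length(errors)) {
    stop("invalid study config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  merged$seed <- as.integer(merged$seed)
  merged
}

#' Read a study configuration from a YAML file
#'
#' @param path Path to a YAML config file.
#' @return Validated, normalized config.
#' @export
read_study_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full OSAT-versus-telescoped study
#'
#' Executes, under one derived seed schedule: the OSAT step-1 campaign, the
#' OSAT step-2 campaign on the intermediate-mixture reservoir, a step-2
#' control campaign on a pure-aminophenol reservoir, and the telescoped
#' four-variable campaign. Computes mass-flow breakdowns at each optimum
#' (the OSAT-combined breakdown chains the two steps at their separately
#' found optima) and assembles the comparison table and an importance
#' summary. When `config$out_dir` is set, writes per-campaign experiment
#' CSVs, campaign JSONs, the comparison table CSV and a manifest embedding
#' the config hash and seed. Idempotent for a fixed config.
#'
#' @param config A study config (validated by [validate_config()]).
#' @return Invisibly, the study bundle: list with `osat`, `step2_pure`,
#'   `telescoped`, `comparison`, `importance`, `errors` (named list of
#'   stage failures, empty on success), `config`, `hash`.
#' @export
run_study <- function(config = default_study_config()) {
  config <- validate_config(config)
  params <- kinetic_preset(config$kinetics)
  osat_rig <- rig_preset(config$rig_osat)
  tele_rig <- rig_preset(config$rig_telescoped)
  noise <- noise_model(config$noise$sigma_abs, config$noise$p_fault)
  cc <- config$campaign
  cfg_osat <- campaign_config(budget = cc$budget_osat,
                              monitoring_interval = cc$monitoring_interval,
                              plateau_window = cc$plateau_window,
                              plateau_delta = cc$plateau_delta,
                              hours_per_experiment = cc$hours_per_experiment)
  cfg_tele <- campaign_config(budget = cc$budget_telescoped,
                              monitoring_interval = cc$monitoring_interval,
                              plateau_window = cc$plateau_window,
                              plateau_delta = cc$plateau_delta,
                              hours_per_experiment = cc$hours_per_experiment)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  osat <- stage("osat", run_osat(params = params, preset = osat_rig,
                                 noise = noise, config1 = cfg_osat,
                                 config2 = cfg_osat, seed = config$seed))
  pure_feed <- stream_composition(
    c2 = design_space_preset("step1")$variables$C1$lower,
    water = params$C_w0, liquid_flow = 0.5)
  step2_pure <- stage("step2_pure", run_campaign(
    "step2", params = params, preset = osat_rig, feed = pure_feed,
    noise = noise, config = cfg_osat,
    seed = derive_seed(config$seed, "pure")))
  tele <- stage("telescoped", run_campaign(
    "telescoped", params = params, preset = tele_rig, noise = noise,
    config = cfg_tele, seed = derive_seed(config$seed, "tele")))

  comparison <- importance <- NULL
  if (is.null(errors$osat) && is.null(errors$telescoped)) {
    comparison <- stage("comparison", {
      bd1 <- mass_flows("step1", osat$step1$best_cond, osat_rig,
                        osat$im_feed)
      bd2 <- mass_flows("step2", osat$step2_im$best_cond, osat_rig,
                        osat$optimum_streams$step2, feed = osat$im_feed)
      bd_comb <- chained_osat_breakdown(osat, osat_rig, params)
      tele_out <- simulate_telescoped(tele$best_cond, catalyst_state(),
                                      params, tele_rig)
      bd_tel <- mass_flows("telescoped", tele$best_cond, tele_rig,
                           tele_out$step2)
      comparison_report(list(
        osat_step1 = list(breakdown = bd1,
                          experiments = osat$step1$experiments_to_optimum),
        osat_step2 = list(breakdown = bd2,
                          experiments = osat$step2_im$experiments_to_optimum),
        osat_combined = list(
          breakdown = bd_comb,
          experiments = osat$step1$experiments_to_optimum +
            osat$step2_im$experiments_to_optimum),
        telescoped = list(breakdown = bd_tel,
                          experiments = tele$experiments_to_optimum)))
    })
    importance <- stage("importance", rbind(
      cbind(campaign = "osat_step1", osat$step1$importance),
      cbind(campaign = "osat_step2_im", osat$step2_im$importance),
      cbind(campaign = "telescoped", tele$importance)))
  }

  bundle <- list(osat = osat, step2_pure = step2_pure, telescoped = tele,
                 comparison = comparison, importance = importance,
                 errors = errors, config = config,
                 hash = config_hash(config))
  if (!is.null(config$out_dir)) write_study_bundle(bundle, config$out_dir)
  invisible(bundle)
}

# Combined OSAT mass flows: the two steps chained at their separate optima.
# Feed streams are step one's (substrate solution + hydrogen) plus the
# anhydride dosed at the step-2 optimum equivalents; the product rate comes
# from running the step-1 optimum outlet through step two at its optimum
# temperature and equivalents at flow continuity.
chained_osat_breakdown <- function(osat, preset, params) {
  cond2 <- osat$step2_im$best_cond
  out <- simulate_step2(osat$im_feed, cond2, params, preset)
  bd1 <- mass_flows("step1", osat$step1$best_cond, preset, osat$im_feed)
  Q1 <- osat$step1$best_cond[["Q1"]]
  anh_rate <- cond2[["equiv3"]] * osat$im_feed$conc[["c2"]] *
    MOLAR_MASS[["c3"]] * Q1 * 60 / 1000
  rows <- rbind(bd1$materials,
                data.frame(material = "acetic anhydride", rate = anh_rate,
                           solvent = FALSE))
  prod <- out$conc[["c4"]] * MOLAR_MASS[["c4"]] * Q1 * 60 / 1000
  mass_flow_breakdown(rows, prod)
}

write_study_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(hash = bundle$hash, seed = bundle$config$seed)
  camps <- list(osat_step1 = bundle$osat$step1,
                osat_step2_im = bundle$osat$step2_im,
                step2_pure = bundle$step2_pure,
                telescoped = bundle$telescoped)
  for (nm in names(camps)) {
    cp <- camps[[nm]]
    if (is.null(cp)) next
    rec <- cbind(config_hash = meta$hash, study_seed = meta$seed, cp$records)
    utils::write.csv(rec, file.path(out_dir, paste0(nm, "_experiments.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      c(meta, list(mode = cp$mode, best_cond = as.list(cp$best_cond),
                   best_yield = cp$best_y,
                   n_experiments = cp$n_experiments,
                   experiments_to_optimum = cp$experiments_to_optimum,
                   termination_reason = cp$termination_reason,
                   importance = cp$importance)),
      file.path(out_dir, paste0(nm, "_campaign.json")),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$comparison)) {
    utils::write.csv(cbind(config_hash = meta$hash, bundle$comparison),
                     file.path(out_dir, "comparison_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$importance)) {
    utils::write.csv(cbind(config_hash = meta$hash, bundle$importance),
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
  }
  jsonlite::write_json(c(meta, list(config = bundle$config,
                                    errors = bundle$errors)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
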