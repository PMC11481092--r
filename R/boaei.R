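#' Adaptive expected-improvement settings
#'
#' The exploration offset `xi` (in standardized objective units) is walked
#' geometrically through the campaign on a success/failure signal: after a
#' *successful* proposal — one whose measurement lands within the plateau
#' delta of the running best, i.e. the surrogate's peak region is real —
#' `xi` shrinks by `adapt_down` (exploit and polish); after a *failed* one —
#' the surrogate was wrong about that region — `xi` grows by `adapt_up`
#' (explore), clipped to `[xi_min, xi_max]`. Re-sampling near the optimum is
#' deliberately not treated as stagnation: near a (noisy) optimum genuine
#' improvements become rare, and a law that raises `xi` on every
#' non-improving experiment saturates within a handful of runs and sends
#' proposals into regions the surrogate has already ruled out. The mild
#' default up-multiplier grows exploration pressure on the timescale of a
#' whole campaign. This is the package's concrete adaptation law for an
#' adaptive-EI optimizer.
#'
#' @param xi0 Initial offset.
#' @param xi_min,xi_max Clipping bounds.
#' @param adapt_up Multiplier applied on stagnation (`>= 1`).
#' @param adapt_down Multiplier applied on improvement (`<= 1`).
#' @return An object of class `flowbo_acq`.
#' @export
acquisition_config <- function(xi0 = 0.05, xi_min = 0.005, xi_max = 0.15,
                               adapt_up = 1.15, adapt_down = 0.7) {
  stopifnot(0 <= xi_min, xi_min <= xi0, xi0 <= xi_max,
            adapt_up >= 1, adapt_down <= 1, adapt_down > 0)
  structure(list(xi0 = xi0, xi_min = xi_min, xi_max = xi_max,
                 adapt_up = adapt_up, adapt_down = adapt_down),
            class = "flowbo_acq")
}

#' Expected improvement acquisition
#'
#' For maximization, with `z = (mu - best_y - xi) / sd`:
#' `EI = (mu - best_y - xi) * pnorm(z) + sd * dnorm(z)`; at `sd = 0` it
#' degenerates to `max(0, mu - best_y - xi)`.
#'
#' @param mean,sd Posterior mean and standard deviation (vectors).
#' @param best_y Incumbent best observed objective.
#' @param xi Exploration offset (`>= 0`).
#' @return EI values, same length as `mean`.
#' @export
expected_improvement <- function(mean, sd, best_y, xi = 0) {
  stopifnot(xi >= 0)
  imp <- mean - best_y - xi
  ei <- pmax(imp, 0)  # sd == 0 branch
  pos <- sd > 0
  if (any(pos)) {
    z <- imp[pos] / sd[pos]
    ei[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(ei, 0)
}

#' Walk the adaptive exploration offset along a campaign history
#'
#' @param config An [acquisition_config()].
#' @param successful Logical vector: for each refinement experiment so far,
#'   did its measurement land within the plateau delta of (or above) the
#'   running best? Empty history returns `xi0`.
#' @return The `xi` to use for the next proposal.
#' @export
adapt_xi <- function(config, successful) {
  xi <- config$xi0
  for (im in successful) {
    xi <- xi * if (isTRUE(im)) config$adapt_down else config$adapt_up
    xi <- min(max(xi, config$xi_min), config$xi_max)
  }
  xi
}

#' Propose the next experiment by maximizing EI
#'
#' Multistart local search over the unit hypercube: 32 seeded uniform starts
#' plus 32 Gaussian perturbations of the incumbent (sd 0.1, clipped), each
#' polished with L-BFGS-B. Near-ties (EI within `1e-9` of the maximum) are
#' broken by the smallest unit-scaled lexicographic order. If the whole
#' acquisition surface is flat at zero, falls back to the point of maximum
#' posterior sd among 1024 seeded samples (pure exploration), flagged in the
#' result.
#'
#' @param model A fitted `flowbo_gp`.
#' @param space A `flowbo_space`.
#' @param best_y Incumbent best objective.
#' @param xi Exploration offset.
#' @param seed Integer seed for the starts.
#' @param incumbent Unit-scaled location of the incumbent best (optional;
#'   centre of the cube if absent).
#' @return List with `cond` (physical units), `x_unit`, `ei`, and
#'   `fallback` flag.
#' @export
propose <- function(model, space, best_y, xi, seed = 1L, incumbent = NULL) {
  n <- space$n
  if (is.null(incumbent)) incumbent <- rep(0.5, n)
  neg_ei <- function(x) {
    p <- gp_predict(model, matrix(x, nrow = 1))
    -expected_improvement(p$mean, p$sd, best_y, xi)
  }
  starts <- with_seed(seed, {
    rand <- matrix(stats::runif(32 * n), ncol = n)
    near <- matrix(pmin(pmax(rep(incumbent, each = 32) +
                               stats::rnorm(32 * n, 0, 0.1), 0), 1), ncol = n)
    rbind(rand, near)
  })
  cand_x <- vector("list", nrow(starts))
  cand_ei <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[i, ], neg_ei, method = "L-BFGS-B",
                   lower = rep(0, n), upper = rep(1, n),
                   control = list(maxit = 100)),
      error = function(e) list(par = starts[i, ],
                               value = neg_ei(starts[i, ])))
    cand_x[[i]] <- pmin(pmax(opt$par, 0), 1)
    cand_ei[i] <- -opt$value
  }
  best_ei <- max(cand_ei)
  if (best_ei <= 1e-12) {
    # flat acquisition: pure exploration at the max-sd sample point
    Xs <- with_seed(derive_seed(seed, "explore"),
                    matrix(stats::runif(1024 * n), ncol = n))
    sds <- gp_predict(model, Xs)$sd
    x <- Xs[which.max(sds), ]
    return(list(cond = from_unit(space, x), x_unit = x, ei = 0,
                fallback = TRUE))
  }
  ties <- which(cand_ei >= best_ei - 1e-9)
  tie_mat <- do.call(rbind, cand_x[ties])
  pick <- ties[do.call(order, as.data.frame(tie_mat))[1]]
  x <- cand_x[[pick]]
  list(cond = from_unit(space, x), x_unit = x, ei = cand_ei[pick],
       fallback = FALSE)
}

#' Campaign control settings
#'
#' @param budget Maximum number of optimization experiments (LHS plus
#'   refinement; monitoring and rejected runs do not count).
#' @param monitoring_interval Run a standard-condition monitoring experiment
#'   after every this many optimization experiments.
#' @param plateau_window Stop after this many consecutive refinement
#'   experiments without improvement beyond `plateau_delta`.
#' @param plateau_delta Minimum improvement of the running best (yield
#'   fraction) that counts as progress.
#' @param sd_threshold Optional: also stop once the maximum posterior sd over
#'   a 1024-point sample drops below this value (`NULL` disables, mirroring
#'   manual termination).
#' @param hours_per_experiment Rig time consumed by each experiment (of any
#'   kind), in hours.
#' @param failure_at_experiment Optimization-experiment index after which an
#'   abrupt catalyst-failure event strikes (`NA` = never).
#' @param shutdown_every_h Insert a shutdown/restart (with its 5% activity
#'   recovery) whenever cumulative time on stream crosses a multiple of this
#'   many hours (`Inf` = never).
#' @return An object of class `flowbo_campaign_config`.
#' @export
campaign_config <- function(budget = 25L, monitoring_interval = 4L,
                            plateau_window = 5L, plateau_delta = 0.005,
                            sd_threshold = NULL, hours_per_experiment = 2,
                            failure_at_experiment = NA_integer_,
                            shutdown_every_h = Inf) {
  stopifnot(budget >= 2, monitoring_interval >= 2, plateau_window >= 1,
            plateau_delta >= 0, hours_per_experiment > 0)
  structure(list(budget = as.integer(budget),
                 monitoring_interval = as.integer(monitoring_interval),
                 plateau_window = as.integer(plateau_window),
                 plateau_delta = plateau_delta, sd_threshold = sd_threshold,
                 hours_per_experiment = hours_per_experiment,
                 failure_at_experiment = failure_at_experiment,
                 shutdown_every_h = shutdown_every_h),
            class = "flowbo_campaign_config")
}

#' Decide whether a campaign should stop
#'
#' Never stops during the initialization design. Afterwards, stops when (a)
#' the running best has not improved by more than `plateau_delta` over the
#' last `plateau_window` refinement experiments, (b) the model's maximum
#' posterior sd over a seeded 1024-point sample is below `sd_threshold`
#' (only if set), or (c) the budget of optimization experiments is spent.
#'
#' @param objectives Measured objective of each optimization experiment so
#'   far, in execution order.
#' @param n_init Number of initialization (LHS) experiments.
#' @param config A [campaign_config()].
#' @param model Optional fitted `flowbo_gp` (needed for the sd rule).
#' @param space Optional `flowbo_space` (needed for the sd rule).
#' @return List with `stop` (logical) and `reason`
#'   (`"plateau"`, `"low_uncertainty"`, `"budget"`, or `NA`).
#' @export
should_terminate <- function(objectives, n_init, config, model = NULL,
                             space = NULL) {
  n <- length(objectives)
  if (n >= config$budget) return(list(stop = TRUE, reason = "budget"))
  if (n <= n_init) return(list(stop = FALSE, reason = NA_character_))
  # consecutive non-improving refinement streak
  best_so_far <- cummax(objectives)
  ref_improved <- diff(best_so_far)[n_init:(n - 1)] > config$plateau_delta
  streak <- 0L
  for (im in rev(ref_improved)) {
    if (im) break
    streak <- streak + 1L
  }
  if (streak >= config$plateau_window) {
    return(list(stop = TRUE, reason = "plateau"))
  }
  if (!is.null(config$sd_threshold) && !is.null(model) && !is.null(space)) {
    Xs <- with_seed(20480L, matrix(stats::runif(1024 * space$n),
                                   ncol = space$n))
    if (max(gp_predict(model, Xs)$sd) < config$sd_threshold) {
      return(list(stop = TRUE, reason = "low_uncertainty"))
    }
  }
  list(stop = FALSE, reason = NA_character_)
}

# Execute one physical experiment on the rig (or a user-supplied objective
# function) and wrap it in a record row.
run_experiment <- function(mode, cond, state, params, preset, feed, noise,
                           obj_fun = NULL) {
  truth <- if (is.null(obj_fun)) {
    rig_truth(mode, cond, state, params, preset, feed)
  } else {
    list(yield_step1 = NA_real_, yield_step2 = obj_fun(cond))
  }
  m <- measure(truth, noise)
  list(truth = truth, measurement = m,
       objective = if (mode == "step1") m$yield_step1 else m$yield_step2)
}

#' Run a closed-loop BOAEI campaign on the virtual rig
#'
#' Executes the Latin hypercube initialization (`2n + 1` experiments), then
#' the fit-adapt-propose-measure refinement loop until [should_terminate()]
#' fires. A monitoring experiment at fixed standard conditions (bound
#' midpoints) is inserted after every `monitoring_interval` optimization
#' experiments; monitoring and rejected records are kept in the log but
#' never enter the surrogate's training data. A measurement that reads below
#' 2% yield while the operator expects more (a model prediction above 10%;
#' during initialization, a visibly blank chromatogram) is treated as a
#' failed gas-liquid separation: the record is marked rejected and the same
#' conditions are repeated (at most twice, then the reading is accepted as
#' genuine). The catalyst loses activity with time on stream throughout, and
#' scheduled failure/shutdown events from the config are applied. Fully
#' reproducible for a fixed seed.
#'
#' @param mode `"step1"`, `"step2"` or `"telescoped"`.
#' @param space Design space; defaults to the preset matching `mode`.
#' @param params,preset Kinetics and rig presets.
#' @param feed Feed stream (step-2 mode only).
#' @param noise A [noise_model()].
#' @param acq An [acquisition_config()].
#' @param config A [campaign_config()].
#' @param deact A [deactivation_model()].
#' @param objective Optional function `cond -> yield fraction` replacing the
#'   virtual rig (mode `"custom"`); used for benchmarking the optimizer on
#'   surfaces with a known optimum.
#' @param seed Integer seed; drives the LHS, measurement noise, GP restarts
#'   and proposal starts through derived streams.
#' @return An object of class `flowbo_campaign`: list with `records` (data
#'   frame, one row per executed experiment of any kind), `best_cond`,
#'   `best_y`, `experiments_to_optimum`, `termination_reason`, `importance`,
#'   `model` (final surrogate), `mode`, `seed`.
#' @export
run_campaign <- function(mode = c("step1", "step2", "telescoped", "custom"),
                         space = NULL, params = kinetic_preset(),
                         preset = NULL, feed = NULL,
                         noise = noise_model(), acq = acquisition_config(),
                         config = campaign_config(),
                         deact = deactivation_model(), objective = NULL,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "custom") {
    stopifnot(is.function(objective), !is.null(space))
  } else {
    objective <- NULL
  }
  space <- space %||% design_space_preset(switch(mode, step1 = "step1",
                                                 step2 = "step2-im",
                                                 telescoped = "telescoped"))
  preset <- preset %||%
    rig_preset(if (mode == "telescoped") "telescoped" else "osat")
  if (mode == "step2" && is.null(feed)) {
    feed <- intermediate_mixture(params = params, preset = preset)
  }
  n_init <- 2L * space$n + 1L
  if (config$budget < n_init) {
    stop("budget must cover the 2n+1 initialization experiments",
         call. = FALSE)
  }
  standard_cond <- from_unit(space, rep(0.5, space$n))
  X_lhs <- lhs_design(space, derive_seed(seed, "lhs"))

  state <- catalyst_state()
  records <- list()
  opt_X <- NULL       # unit-scaled accepted optimization inputs
  opt_y <- numeric(0) # their measured objectives
  xi_hist <- logical(0)
  model <- NULL
  last_xi <- NA_real_
  last_ei <- NA_real_
  reason <- "budget"

  add_record <- function(cond, kind, res, opt_index) {
    row <- as.list(cond)
    row$index <- length(records) + 1L
    row$opt_index <- opt_index
    row$kind <- kind
    row$yield_step1 <- res$measurement$yield_step1
    row$yield_step2 <- res$measurement$yield_step2
    row$objective <- res$objective
    row$blank_flag <- res$measurement$blank_flag
    row$activity <- state$activity
    row$time_on_stream <- state$time_on_stream
    row$xi <- last_xi
    row$ei <- last_ei
    records[[length(records) + 1L]] <<- row
  }

  tick_catalyst <- function(failure = FALSE) {
    t_next <- state$time_on_stream + config$hours_per_experiment
    shutdown <- is.finite(config$shutdown_every_h) &&
      (t_next %/% config$shutdown_every_h >
         state$time_on_stream %/% config$shutdown_every_h)
    state <<- advance_catalyst(state, config$hours_per_experiment, deact,
                               failure = failure, shutdown = shutdown)
    state$experiments_run <- state$experiments_run + 1L
  }

  suspicious <- function(res, cond_unit) {
    objective <- res$objective
    if (is.na(objective) || objective >= 0.02) return(FALSE)
    if (is.null(model)) {
      # no surrogate yet: the operator reads the chromatogram itself, and a
      # separation failure (no peaks at all) is distinguishable from a
      # genuinely unreactive condition (substrate peak still present)
      return(isTRUE(res$measurement$blank_flag))
    }
    gp_predict(model, matrix(cond_unit, nrow = 1))$mean > 0.10
  }

  # Execute one optimization experiment (with rejection-repeat and
  # monitoring bookkeeping); returns its measured objective.
  do_opt_experiment <- function(cond, cond_unit) {
    attempts <- 0L
    repeat {
      res <- run_experiment(mode, cond, state, params, preset, feed, noise,
                            objective)
      failure <- !is.na(config$failure_at_experiment) &&
        length(opt_y) + 1L == config$failure_at_experiment
      if (attempts < 2L && suspicious(res, cond_unit)) {
        add_record(cond, "rejected", res, NA_integer_)
        tick_catalyst(failure = FALSE)
        attempts <- attempts + 1L
        next
      }
      kind <- if (length(opt_y) < n_init) "lhs" else "refinement"
      add_record(cond, kind, res, length(opt_y) + 1L)
      opt_X <<- rbind(opt_X, cond_unit)
      opt_y <<- c(opt_y, res$objective)
      tick_catalyst(failure = failure)
      break
    }
    if (length(opt_y) %% config$monitoring_interval == 0L) {
      res_m <- run_experiment(mode, standard_cond, state, params, preset,
                              feed, noise, objective)
      add_record(standard_cond, "monitoring", res_m, NA_integer_)
      tick_catalyst()
    }
    invisible(NULL)
  }

  with_seed(derive_seed(seed, "campaign"), {
    for (i in seq_len(n_init)) {
      do_opt_experiment(X_lhs[i, ], to_unit(space, X_lhs[i, ]))
    }
    repeat {
      model <- gp_fit(opt_X, opt_y, seed = derive_seed(seed, "gp"))
      term <- should_terminate(opt_y, n_init, config, model, space)
      if (term$stop) { reason <- term$reason; break }
      best_i <- which.max(opt_y)
      xi_raw <- adapt_xi(acq, xi_hist)
      # xi is specified in standardized objective units
      last_xi <- xi_raw
      best_prev <- max(opt_y)
      prop <- propose(model, space, best_y = best_prev,
                      xi = xi_raw * model$y_sd,
                      seed = derive_seed(seed, length(opt_y)),
                      incumbent = opt_X[best_i, ])
      last_ei <- prop$ei
      do_opt_experiment(prop$cond, prop$x_unit)
      xi_hist <- c(xi_hist,
                   opt_y[length(opt_y)] >= best_prev - config$plateau_delta)
    }
  })

  rec_df <- do.call(rbind, lapply(records, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  best_i <- which.max(opt_y)
  best_y <- opt_y[best_i]
  eto <- which(opt_y >= best_y - 0.01)[1]
  structure(list(
    records = rec_df,
    best_cond = from_unit(space, opt_X[best_i, ]),
    best_y = best_y,
    n_experiments = length(opt_y),
    experiments_to_optimum = as.integer(eto),
    termination_reason = reason,
    importance = gp_importance(model, space),
    model = model, mode = mode, space = space, seed = seed
  ), class = "flowbo_campaign")
}

#' @export
print.flowbo_campaign <- function(x, ...) {
  cat(sprintf(
    "BOAEI campaign (%s): %d optimization experiments, best yield %.1f%%\n",
    x$mode, x$n_experiments, 100 * x$best_y))
  cat(sprintf("  reached within 1 point of the final best after %d experiments (%s termination)\n",
              x$experiments_to_optimum, x$termination_reason))
  invisible(x)
}

#' Run the one-step-at-a-time (OSAT) study
#'
#' Optimizes step one on the packed-bed rig, freezes its best conditions,
#' builds the intermediate-mixture reservoir from the noise-free step-1
#' outlet at those conditions (~65:35 aminophenol:nitrophenol at the
#' calibrated optimum), then optimizes step two on that reservoir with
#' consumption of the aminophenol as the objective. Returns both campaign
#' results together with the streams needed for mass-flow accounting.
#'
#' @param params Kinetics preset.
#' @param preset OSAT rig preset.
#' @param noise,acq,deact Shared campaign components.
#' @param config1,config2 Campaign configs for the two campaigns.
#' @param seed Integer seed; the two campaigns use derived streams.
#' @return List with `step1`, `step2_im` (`flowbo_campaign`s), `im_feed`,
#'   and `optimum_streams` (step-1 and step-2 outlet streams at the two
#'   optima).
#' @export
run_osat <- function(params = kinetic_preset(), preset = rig_preset("osat"),
                     noise = noise_model(), acq = acquisition_config(),
                     config1 = campaign_config(budget = 25L),
                     config2 = campaign_config(budget = 25L),
                     deact = deactivation_model(), seed = 1L) {
  step1 <- run_campaign("step1", params = params, preset = preset,
                        noise = noise, acq = acq, config = config1,
                        deact = deact, seed = derive_seed(seed, "osat1"))
  im <- simulate_step1(step1$best_cond, catalyst_state(), params, preset)
  step2 <- run_campaign("step2", params = params, preset = preset,
                        feed = im, noise = noise, acq = acq,
                        config = config2, deact = deact,
                        seed = derive_seed(seed, "osat2"))
  out2 <- simulate_step2(im, step2$best_cond, params, preset)
  list(step1 = step1, step2_im = step2, im_feed = im,
       optimum_streams = list(step1 = im, step2 = out2))
}
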