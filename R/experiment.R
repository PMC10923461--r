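# Reproducible experiment driver: a flat declarative config selects one of
# the package's analysis tasks; outputs are columnar text plus a JSON
# metadata sidecar. Also provides small deterministic fixtures for testing
# the metrics pipeline.

experiment_tasks <- c("simulate", "dde", "theory", "ifa", "ifa-theory",
                      "stability", "regimes")

#' Run a declarative experiment
#'
#' Executes one of the package's analysis tasks from a flat configuration
#' (named list, or path to a `key = value` file). Common keys: `task` (one
#' of `simulate`, `dde`, `theory`, `ifa`, `ifa-theory`, `stability`,
#' `regimes`), `out_dir` (optional; when given, columnar results and a JSON
#' metadata sidecar are written there), `seed`, and task-specific keys such
#' as `I_E`, `duration`, `dt`, `N`, `slope_m`, `repetitions`, `with_reset`.
#' Presets: `preset = "strong-drive-cycle"` evaluates the constant-drive
#' cycle theory with and without reset at `I_E = 3.6`;
#' `preset = "ifa-slopes"` computes the theoretical IFA slopes for ramp
#' slopes 0.4, 0.2, 0.1 per ms, optionally with matched reduced-size
#' simulations (`with_sim = TRUE`).
#'
#' @param config named list or path to a flat key-value config file.
#' @return task-dependent result list, invisibly when written to disk.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!is.list(config) || !length(config)) stop("empty or invalid config")
  if (!is.null(config$preset)) return(run_preset(config))
  known <- c("task", "out_dir", "seed", "I_E", "duration", "dt", "N",
             "slope_m", "repetitions", "with_reset", "baseline", "plateau",
             "t_plateau", "IE_min", "IE_max", "IE_step", "preset",
             "with_sim")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  task <- config$task
  if (is.null(task) || !task %in% experiment_tasks)
    stop("config must name a task, one of: ",
         paste(experiment_tasks, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  p <- dimensionless_params(N = as.integer(config$N %||% 10000L))
  res <- switch(task,
    simulate = {
      sim <- simulate_network(
        p, constant_drive(config$I_E %||% 4, config$duration %||% 1000),
        dt = config$dt %||% 0.01, seed = seed)
      list(sim = sim, f_net = network_frequency_psd(sim)$f_net,
           unit = unit_stats(sim))
    },
    dde = {
      tr <- integrate_dde(
        p, constant_drive(config$I_E %||% 3.6, config$duration %||% 300),
        dt = config$dt %||% 0.005,
        with_reset = isTRUE(config$with_reset))
      list(trajectory = tr, regime = classify_regime(tr))
    },
    theory = {
      grid <- seq(config$IE_min %||% 3, config$IE_max %||% 9,
                  by = config$IE_step %||% 0.25)
      tab <- do.call(rbind, lapply(grid, function(IE)
        as.data.frame(gd_constant_solution(IE, p,
          with_reset = !isFALSE(config$with_reset)))))
      list(table = tab)
    },
    `ifa-theory` = {
      d <- make_spw_drive(config$baseline %||% 0.74,
                          config$plateau %||% 8.9,
                          config$slope_m %||% 0.4,
                          t_plateau = config$t_plateau %||% 20)
      fit <- gd_ifa_theory(d, p)
      list(fit = fit, chain = attr(fit, "chain"))
    },
    ifa = {
      d <- make_spw_drive(config$baseline %||% 0.74,
                          config$plateau %||% 8.9,
                          config$slope_m %||% 0.4,
                          t_plateau = config$t_plateau %||% 20)
      reps <- as.integer(config$repetitions %||% 10L)
      series <- lapply(seq_len(reps), function(k) {
        sim <- simulate_network(p, d, dt = config$dt %||% 0.01,
                                seed = seed + k - 1L)
        inst_freq_peaks(sim)
      })
      list(fit = ifa_slope(series), series = series)
    },
    stability = {
      hp <- hopf_point(p)
      list(hopf = hp)
    },
    regimes = {
      grid <- seq(config$IE_min %||% 0.3, config$IE_max %||% 4,
                  by = config$IE_step %||% 0.3)
      labs <- vapply(grid, function(IE) {
        tr <- integrate_dde(p, constant_drive(IE, 400))
        classify_regime(tr)$label
      }, "")
      list(table = data.frame(I_E = grid, regime = labs))
    })
  if (!is.null(config$out_dir)) {
    write_experiment(res, task, config, seed)
    return(invisible(res))
  }
  res
}

run_preset <- function(config) {
  preset <- config$preset
  p <- dimensionless_params()
  if (preset == "strong-drive-cycle") {
    no_r <- gd_constant_solution(3.6, p, with_reset = FALSE)
    with_r <- gd_constant_solution(3.6, p, with_reset = TRUE)
    out <- list(f_net_no_reset = no_r$f_net, f_net_with_reset = with_r$f_net,
                no_reset = no_r, with_reset = with_r)
  } else if (preset == "ifa-slopes") {
    slopes <- c(0.4, 0.2, 0.1)
    chi_th <- vapply(slopes, function(m)
      gd_ifa_theory(make_spw_drive(0.74, 8.9, m), p)$chi_ifa, 0)
    out <- list(table = data.frame(slope_m = slopes, chi_ifa_theory = chi_th))
    if (isTRUE(config$with_sim)) {
      ps <- dimensionless_params(N = as.integer(config$N %||% 1000L))
      reps <- as.integer(config$repetitions %||% 10L)
      seed <- as.integer(config$seed %||% 1L)
      chi_sim <- vapply(slopes, function(m) {
        d <- make_spw_drive(0.74, 8.9, m)
        series <- lapply(seq_len(reps), function(k)
          inst_freq_peaks(simulate_network(ps, d, seed = seed + k - 1L)))
        ifa_slope(series)$chi_ifa
      }, 0)
      out$table$chi_ifa_sim <- chi_sim
    }
  } else stop("unknown preset: ", preset)
  if (!is.null(config$out_dir)) {
    write_experiment(out, paste0("preset_", preset), config,
                     as.integer(config$seed %||% 1L))
    return(invisible(out))
  }
  out
}

write_experiment <- function(res, task, config, seed) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  for (nm in names(res)) {
    x <- res[[nm]]
    if (is.data.frame(x))
      write.table(format(x, digits = 10),
                  file.path(config$out_dir, paste0(task, "_", nm, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    else if (inherits(x, "sim_result"))
      write_sim_result(x, config$out_dir, nm)
    else if (inherits(x, "dde_trajectory"))
      write_dde_trajectory(x, file.path(config$out_dir,
                                        paste0(task, "_", nm, ".tsv")))
  }
  meta <- list(task = task, seed = seed,
               config = config[setdiff(names(config), "out_dir")],
               package_version = as.character(utils::packageVersion("ripplenet")),
               wall_time_s = as.numeric(Sys.time() - t0, units = "secs"),
               timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, file.path(config$out_dir,
                                       paste0(task, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(list())
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic test fixtures
#'
#' Small, fast, seeded inputs for exercising the metrics pipeline:
#' `"chirp"` -- a rate trace whose oscillation sweeps linearly from 250 to
#' 150 Hz after a flat baseline; `"sparse-synchrony"` -- a short
#' constant-drive simulation of a 100-unit network in the sparsely
#' synchronized regime; `"flat"` -- a constant-rate trace with white
#' fluctuations.
#'
#' @param kind fixture tag.
#' @param seed integer seed.
#' @return for rate fixtures, a list with `rate`, `dt`, and the ground
#'   truth; for `"sparse-synchrony"`, a `sim_result`.
#' @export
make_fixture <- function(kind = c("chirp", "sparse-synchrony", "flat"),
                         seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    chirp = {
      dt <- 0.1
      t_base <- 200; t_ev <- 100
      t <- seq(0, t_base + t_ev - dt, by = dt)
      f0 <- 250; f1 <- 150
      inst_f <- ifelse(t < t_base, 0,
                       f0 + (f1 - f0) * (t - t_base) / t_ev)   # Hz
      phase <- 2 * pi * cumsum(inst_f) * dt / 1000
      rate <- 20 + 200 * ifelse(t >= t_base, 1 + sin(phase), 0) +
        rnorm(length(t), 0, 1)
      list(rate = pmax(rate, 0), dt = dt, t = t,
           truth = data.frame(t = t, f = inst_f))
    },
    `sparse-synchrony` = {
      p <- dimensionless_params(N = 100L)
      simulate_network(p, constant_drive(4.2, 400), dt = 0.02, seed = seed)
    },
    flat = {
      dt <- 0.1
      t <- seq(0, 400 - dt, by = dt)
      list(rate = pmax(50 + rnorm(length(t), 0, 5), 0), dt = dt, t = t)
    })
}
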