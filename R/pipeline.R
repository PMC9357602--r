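#' Read a pipeline run configuration
#'
#' Configurations are YAML files with sectioned blocks (\code{model},
#' \code{kernel}, \code{scenario}, \code{analysis}); see the packaged example
#' under \code{inst/extdata/example_config.yaml}.
#'
#' @param path path to a YAML config file.
#' @return the configuration as a nested list, classed
#'   \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the parameter invariants of every block (positivity of
#' \eqn{\epsilon^2, L^2}, positive-delay admissibility of the kernel
#' truncation window, grid sanity) without running anything.
#'
#' @param cfg a configuration list (from \code{\link{read_run_config}} or
#'   built in code).
#' @return character vector of diagnostics; empty when the configuration is
#'   valid.
#' @export
validate_run_config <- function(cfg) {
  diags <- character(0)
  say <- function(...) diags <<- c(diags, paste0(...))
  mo <- cfg$model
  if (is.null(mo)) {
    say("model: block missing")
  } else {
    if (is.null(mo$kinetics) || !mo$kinetics %in% c("LI", "GM1", "GM2"))
      say("model$kinetics: must be one of LI, GM1, GM2")
    if (!is.null(mo$eps2) && mo$eps2 <= 0) say("model$eps2: must be > 0")
    if (!is.null(mo$L2) && mo$L2 <= 0) say("model$L2: must be > 0")
    if (!is.null(mo$kinetics) && identical(mo$kinetics, "LI") &&
        !is.null(mo$a) && !is.null(mo$b) && mo$a + mo$b <= 0)
      say("model$a, model$b: LI needs a + b > 0")
    if (!is.null(mo$kinetics) && mo$kinetics %in% c("GM1", "GM2") &&
        !is.null(mo$b) && mo$b <= 0)
      say("model$b: GM models need b > 0")
  }
  ke <- cfg$kernel
  if (!is.null(ke)) {
    n <- if (is.null(ke$n)) 3 else ke$n
    if (identical(ke$family, "gaussian") && !is.null(ke$tau) &&
        !is.null(ke$sigma) && ke$tau - n * ke$sigma <= 0)
      say("kernel: tau1 = tau - ", n, "*sigma must be > 0 ",
          "(positive delays only)")
    if (identical(ke$family, "skew_gaussian") && !is.null(ke$mu) &&
        !is.null(ke$omega) && ke$mu - n * ke$omega <= 0)
      say("kernel: tau1 = mu - ", n, "*omega must be > 0 ",
          "(positive delays only)")
  }
  sc <- cfg$scenario
  if (!is.null(sc)) {
    if (!is.null(sc$sigma_IC) && sc$sigma_IC < 0)
      say("scenario$sigma_IC: must be >= 0")
    if (!is.null(sc$m) && sc$m < 3) say("scenario$m: must be >= 3")
    if (!is.null(sc$t_end) && sc$t_end <= 0) say("scenario$t_end: must be > 0")
  }
  an <- cfg$analysis
  known <- c("dispersion", "turing-scan", "table2", "skew-curve", "simulate",
             "time-to-pattern", "tau-sweep")
  if (is.null(an) || is.null(an$type)) {
    say("analysis$type: missing")
  } else if (!an$type %in% known) {
    say("analysis$type: unknown '", an$type, "'")
  }
  diags
}

config_model <- function(cfg) {
  mo <- cfg$model
  rd_model(mo$kinetics, a = mo$a, b = mo$b,
           eps2 = if (is.null(mo$eps2)) 0.001 else mo$eps2,
           L2 = if (is.null(mo$L2)) 4.5 else mo$L2)
}

config_kernel <- function(cfg) {
  ke <- cfg$kernel
  if (is.null(ke)) return(delay_kernel("dirac", tau = 0))
  n <- if (is.null(ke$n)) 3 else ke$n
  switch(ke$family,
    dirac = delay_kernel("dirac", tau = ke$tau, n = n),
    gaussian = delay_kernel("gaussian", tau = ke$tau, sigma = ke$sigma,
                            n = n),
    skew_gaussian = delay_kernel("skew_gaussian", mu = ke$mu,
                                 omega = ke$omega, rho = ke$rho, n = n),
    skew_gaussian_mean = {
      lm_ <- location_from_mean(ke$tau, ke$rho,
                                omega_fraction = ke$omega_fraction, n = n)
      delay_kernel("skew_gaussian", mu = lm_$mu, omega = lm_$omega,
                   rho = ke$rho, n = n)
    },
    stop("unknown kernel family '", ke$family, "'"))
}

#' Run a configured analysis
#'
#' Validates the configuration, dispatches to the selected analysis and
#' writes its outputs (comma-separated tables with \code{#}-prefixed metadata
#' lines) and a machine-readable JSON manifest to \code{out_dir}.
#'
#' @param cfg a config list or a path to a YAML config.
#' @param out_dir output directory, created if needed.
#' @param seed optional seed overriding \code{scenario$seed}.
#' @return (invisibly) a list with the analysis result and the written file
#'   paths.
#' @export
run_analysis <- function(cfg, out_dir, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  diags <- validate_run_config(cfg)
  if (length(diags))
    stop("invalid configuration:\n  ", paste(diags, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$scenario
  if (!is.null(seed)) sc$seed <- seed
  if (is.null(sc$seed)) sc$seed <- 1L
  an <- cfg$analysis
  t0 <- Sys.time()
  model <- config_model(cfg)
  files <- character(0)
  write_tab <- function(df, name, meta) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", meta), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    files <<- c(files, path)
    path
  }
  result <- switch(an$type,
    dispersion = {
      disp <- max_growth_rate(model, config_kernel(cfg),
                              k_max = an$k_max %||% 50L)
      write_tab(disp$table, "dispersion.csv",
                paste0("max_re=", disp$max_re, " argmax_k=", disp$argmax_k))
      disp
    },
    `turing-scan` = {
      scan <- turing_space_scan(
        model, config_kernel(cfg),
        a_grid = seq(an$a_min %||% 0, an$a_max %||% 1.4,
                     length.out = an$na %||% 71L),
        b_grid = seq(an$b_min %||% 0, an$b_max %||% 2,
                     length.out = an$nb %||% 101L),
        k_max = an$k_max %||% 50L)
      G <- expand.grid(a = scan$a, b = scan$b)
      write_tab(data.frame(G, max_re = as.vector(scan$max_re),
                           argmax_k = as.vector(scan$argmax_k)),
                "turing_scan.csv",
                paste0("turing_cells=", scan$turing_cells))
      write_tab(scan$contour_k0, "contour_k0.csv", "Re(lambda_0)=0 line")
      write_tab(scan$contour_knz, "contour_knz.csv",
                "max_k!=0 Re(lambda_k)=0 line")
      scan
    },
    table2 = {
      fr <- an$sigma_fractions %||% c(0.99, 0.2, 0.1)
      disc <- distributed_vs_fixed_discrepancy(
        model, tau = cfg$kernel$tau, sigma_fractions = fr,
        a_window = c(an$a_min %||% 0, an$a_max %||% 1.4),
        b_window = c(an$b_min %||% 0, an$b_max %||% 2),
        grid_shape = c(an$na %||% 71L, an$nb %||% 101L),
        k_max = an$k_max %||% 50L)
      write_tab(data.frame(sigma_fraction = fr, max_abs_diff = unname(disc)),
                "table2.csv",
                paste0("eps2=", model$eps2, " tau=", cfg$kernel$tau))
      disc
    },
    `skew-curve` = {
      cur <- skew_growth_curve(model, rho = cfg$kernel$rho,
                               omega_fraction = cfg$kernel$omega_fraction %||%
                                 0.99,
                               tau_grid = an$tau_grid %||%
                                 seq(0, 0.8, by = 0.05),
                               k_max = an$k_max %||% 50L)
      write_tab(cur, "skew_curve.csv", paste0("rho=", cfg$kernel$rho))
      cur
    },
    simulate = {
      sim <- run_scenario_sim(model, cfg, sc)
      write_tab(data.frame(x = sim$x, u = sim$u[nrow(sim$u), ],
                           v = sim$v[nrow(sim$v), ]),
                "final_profile.csv",
                paste0("t=", max(sim$t), " seed=", sc$seed))
      saveRDS_free_export(sim, out_dir, files)
      sim
    },
    `time-to-pattern` = {
      sim <- run_scenario_sim(model, cfg, sc,
                              stop_threshold = sc$threshold * 1.02)
      ts <- time_to_pattern(sim, sc$threshold)
      amps <- mode_amplitudes(sim$u[nrow(sim$u), ] - sim$steady_state[["u"]])
      kd <- which.max(abs(amps[-1]))
      write_tab(data.frame(T_star = as.numeric(ts),
                           reached = isTRUE(attr(ts, "reached")),
                           dominant_k = kd,
                           spike_count = count_spikes(sim$u[nrow(sim$u), ])),
                "time_to_pattern.csv", paste0("threshold=", sc$threshold))
      ts
    },
    `tau-sweep` = {
      sw <- tau_sweep(model, tau_grid = sc$tau_grid %||% seq(1, 16, 1),
                      sigma_IC = sc$sigma_IC, threshold = sc$threshold,
                      seed = sc$seed,
                      grid = spatial_grid(sc$m %||% 200L),
                      t_max = sc$t_end %||% 600)
      write_tab(sw$table, "tau_sweep.csv",
                paste0("slope=", sw$slope, " intercept=", sw$intercept,
                       " r_squared=", sw$r_squared))
      sw
    })
  manifest <- list(analysis = an$type, seed = sc$seed,
                   config = unclass(cfg),
                   package_version = as.character(
                     utils::packageVersion("turingdelay")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(result = result, files = files,
                 manifest = file.path(out_dir, "manifest.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## text-only export of the space-time fields (x, t, u, v as delimited tables)
saveRDS_free_export <- function(sim, out_dir, files) {
  utils::write.csv(data.frame(t = sim$t), file.path(out_dir, "t.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$u), file.path(out_dir, "u.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$v), file.path(out_dir, "v.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

## build and run the simulator from a scenario block
run_scenario_sim <- function(model, cfg, sc, stop_threshold = NULL) {
  grid <- spatial_grid(sc$m %||% 200L)
  ic <- switch(sc$ic %||% "random",
    random = random_ic(model, grid, sc$sigma_IC %||% 0.01, sc$seed),
    structured_surrogate = structured_ic_surrogate(
      model, grid, amplitude = sc$sigma_IC %||% 0.1),
    steady = {
      ss <- steady_state(model)
      list(u = rep(ss[["u"]], grid$m), v = rep(ss[["v"]], grid$m))
    })
  hist <- if (identical(sc$history %||% "constant", "oscillatory")) {
    history_function(kind = "oscillatory", model = model, grid = grid,
                     r_scale = sc$r_scale %||% sc$sigma_IC %||% 0.01,
                     w = sc$w %||% 1, seed = sc$seed)
  } else {
    NULL
  }
  simulate_rd(model, config_kernel(cfg), ic, t_end = sc$t_end %||% 100,
              grid = grid, bc = sc$bc %||% "neumann", history = hist,
              dt_out = sc$dt_out %||% 0.25,
              stop_threshold = stop_threshold)
}
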