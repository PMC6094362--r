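# Configuration-driven runner, benchmark suite, and report writers.
# A run config is a YAML file with blocks:
#   geometry: amplitude, pitch, n_turns, radius, taper_rate, chirality,
#             head_radius, gap
#   physics:  viscosity, motor_rate
#   numerics: nodes_per_turn, n_head, n_phase, eps_factor
#   task:     one of swim | sweep | optimize | benchmark, plus task options
# All node layouts are deterministic (Fibonacci sphere, uniform centerline
# sampling), so a run is bit-for-bit reproducible from its config.

default_numerics <- function() {
  list(nodes_per_turn = 32, n_head = 600, n_phase = 1,
       eps_factor = microswim_eps_factor())
}

#' Read and validate a run configuration
#'
#' @param path YAML file path.
#' @return A validated list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, path)
}

#' Validate a run configuration list
#'
#' @param cfg a list with \code{geometry}, \code{physics} (optional),
#'   \code{numerics} (optional) and \code{task} blocks.
#' @param path source path, used in error messages.
#' @return The completed config, class \code{"run_config"}.
#' @export
validate_run_config <- function(cfg, path = "<config>") {
  fail <- function(...) stop(path, ": ", ..., call. = FALSE)
  if (!is.list(cfg)) fail("config must be a mapping")
  g <- cfg$geometry
  if (is.null(g)) fail("missing 'geometry' block")
  for (f in c("amplitude", "pitch", "n_turns", "radius", "head_radius"))
    if (is.null(g[[f]]) || !is.numeric(g[[f]]))
      fail("geometry: missing or non-numeric field '", f, "'")
  p <- cfg$physics %||% list()
  n <- utils::modifyList(default_numerics(), cfg$numerics %||% list())
  t <- cfg$task %||% list()
  if (is.null(t$kind) ||
      !t$kind %in% c("swim", "sweep", "optimize", "benchmark"))
    fail("task: 'kind' must be one of swim, sweep, optimize, benchmark")
  fl <- filament_spec(g$amplitude, g$pitch, g$n_turns, g$radius,
                      g$taper_rate %||% 0, g$chirality %||% 1L,
                      g$phase %||% 0)
  asm <- assembly_spec(head_spec(g$head_radius), fl, g$gap %||% 0,
                       p$motor_rate %||% 1, p$viscosity %||% 1)
  structure(list(assembly = asm, numerics = n, task = t, raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a configured run
#'
#' Dispatches on the task kind, writes the result files (JSON for swim and
#' optimize, CSV for sweep and benchmark) together with a provenance
#' record (config echo, package version), and returns the results
#' invisibly.
#'
#' @param config a \code{run_config} (or a path to a YAML config).
#' @param out_dir output directory, created if needed.
#' @param resolution "low", "default" or "high": scales the node counts.
#' @return The task result, invisibly.
#' @export
run <- function(config, out_dir = ".", resolution = "default") {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  num <- config$numerics
  scale <- switch(resolution, low = 0.5, default = 1, high = 2,
                  stop("resolution must be low, default or high"))
  num$nodes_per_turn <- max(8L, as.integer(round(num$nodes_per_turn * scale)))
  num$n_head <- max(60L, as.integer(round(num$n_head * scale)))
  asm <- config$assembly
  task <- config$task
  prov <- list(package = "microswim",
               version = as.character(utils::packageVersion("microswim")),
               units = "nondimensional (mu = b = omega = 1 by default)",
               resolution = resolution, config = config$raw)
  res <- switch(task$kind,
    swim = run_swim(asm, task, num),
    sweep = run_sweep(asm, task, num),
    optimize = run_optimize(asm, task, num),
    benchmark = benchmark_suite(resolution))
  if (task$kind %in% c("sweep", "benchmark")) {
    write_report(res, file.path(out_dir, paste0(task$kind, ".csv")), "csv")
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    jsonlite::write_json(list(provenance = prov, results = res),
                         file.path(out_dir, paste0(task$kind, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = 15,
                         force = TRUE)
  }
  invisible(res)
}

run_swim <- function(asm, task, num) {
  methods <- unlist(task$methods %||% "global")
  out <- list()
  hd <- sphere_coefficients(asm$head$R, asm$mu)
  fl <- asm$filament
  need_parts <- any(methods %in% c("global"))
  parts <- NULL
  if (need_parts) {
    disc <- assemble(asm, num$nodes_per_turn, num$n_head,
                     eps_factor = num$eps_factor)
    parts <- partwise_resistance(disc, mu = asm$mu, n_phase = num$n_phase)
  }
  for (m in methods) {
    sol <- switch(m,
      global = solve_global(assemble(asm, num$nodes_per_turn, num$n_head,
                                     eps_factor = num$eps_factor),
                            asm$omega, mu = asm$mu, parts = parts),
      additive = {
        iso <- isolated_flagellum_matrix(fl, num, asm$mu)
        abc <- axial_coefficients(iso)
        solve_additive(hd$A0, hd$C0, abc["A"], abc["B"], abc["C"],
                       asm$omega)
      },
      `rft-gh` = rft_swim(fl, hd, asm$omega, asm$mu, "gray_hancock"),
      `rft-lighthill` = rft_swim(fl, hd, asm$omega, asm$mu, "lighthill"),
      stop("unknown swim method '", m, "'"))
    out[[m]] <- list(method = m, U = sol$U, Omega = sol$Omega,
                     T_motor = sol$T_motor,
                     residual_force = sol$residual_force,
                     residual_torque = sol$residual_torque,
                     coefficients = as.list(sol$coefficients))
  }
  out
}

isolated_flagellum_matrix <- function(fl, num, mu) {
  d <- filament_discretization(fl, num$nodes_per_turn, fl$phase, x0 = 0)
  resistance_matrix(d, pole = c(fl$L / 2, 0, 0), mu = mu)
}

rft_swim <- function(fl, hd, omega, mu, model_id) {
  abc <- axial_coefficients(filament_resistance_rft(
    fl, drag_coefficients(model_id, fl$lambda, fl$r, mu)))
  solve_additive(hd$A0, hd$C0, abc["A"], abc["B"], abc["C"], omega,
                 method = paste0("rft-", model_id))
}

run_sweep <- function(asm, task, num) {
  grid <- unlist(task$n_turns %||% 1:10)
  sweep_lengths(asm, grid,
                methods = unlist(task$methods %||% c("global", "additive",
                                                     "corrected")),
                nodes_per_turn = num$nodes_per_turn, n_head = num$n_head,
                n_phase = num$n_phase)
}

run_optimize <- function(asm, task, num) {
  optimize_length(asm, metric = task$metric %||% "speed",
                  method = task$method %||% "global",
                  bracket = unlist(task$bracket %||% c(1, 20)),
                  n_grid = task$n_grid %||% 8,
                  nodes_per_turn = num$nodes_per_turn, n_head = num$n_head,
                  n_phase = num$n_phase)
}

#' Validation benchmark suite
#'
#' Regenerates every validation case from scratch and compares against
#' its oracle: Stokes drag and rotation resistance of a sphere, two-sphere
#' screening against the reflections estimate, the stroke-averaged helix
#' zero pattern, RFT helix coefficients against their closed forms, and
#' the model-comparison errors for the reference two-turn swimmer.
#'
#' @param resolution "low", "default" or "high".
#' @return Data frame with columns \code{case}, \code{parameter},
#'   \code{value}, \code{oracle}, \code{rel_error}, \code{tol},
#'   \code{pass}.
#' @export
benchmark_suite <- function(resolution = "default") {
  scale <- switch(resolution, low = 0.5, default = 1, high = 2,
                  stop("resolution must be low, default or high"))
  n_head <- max(60L, as.integer(600 * scale))
  npt <- max(8L, as.integer(32 * scale))
  rows <- list()
  add_row <- function(case, parameter, value, oracle, tol) {
    rel <- if (oracle == 0) abs(value) else abs(value / oracle - 1)
    rows[[length(rows) + 1]] <<- data.frame(
      case = case, parameter = parameter, value = value, oracle = oracle,
      rel_error = rel, tol = tol, pass = rel <= tol)
  }

  # sphere: Stokes' law and rotational resistance
  sph <- resistance_matrix(sphere_nodes(head_spec(1), n_head))
  add_row("sphere", "drag", sph$matrix[1, 1], 6 * pi, 0.01)
  add_row("sphere", "torque", sph$matrix[4, 4], 8 * pi, 0.015)

  # two spheres: screening vs the reflections estimate
  for (rho in c(2.5, 4)) {
    ts <- two_sphere_benchmark(1, rho, n_nodes = max(60L, 400L * scale))
    add_row("two_spheres", paste0("drag_ratio_rho_", rho),
            ts$drag / ts$isolated, two_sphere_reflections(1, rho), 0.03)
  }

  # helix: stroke-averaged zero pattern
  fl <- filament_spec(1, 2.42, 3, 1 / 16)
  gen <- function(ph) filament_discretization(fl, npt, ph, x0 = 0)
  hm <- resistance_matrix(gen, pole = c(fl$L / 2, 0, 0), n_phase = 8)
  off <- helix_pattern_residual(hm$matrix)
  add_row("helix_pattern", "off_pattern_ratio", off, 0, 1e-6)

  # RFT vs closed-form slender-helix coefficients
  gm <- drag_coefficients("gray_hancock", fl$lambda, fl$r)
  abc <- axial_coefficients(filament_resistance_rft(fl, gm, 128 * fl$n_turns))
  cf <- helix_rft_closed_form(fl, gm)
  for (nm in c("A", "B", "C"))
    add_row("rft_helix", nm, abc[[nm]], cf[[nm]], 0.01)

  # reference two-turn swimmer: model-comparison errors
  asm <- assembly_spec(head_spec(2), filament_spec(1, 8, 2, 1 / 16))
  tb <- compare_speed_models(asm, nodes_per_turn = npt, n_head = n_head)
  ref <- c(additive = 9.17, additive_corrected = 1.72,
           rft_gray_hancock = 14.89, rft_gray_hancock_corrected = 1.49,
           rft_lighthill = 42.37, rft_lighthill_corrected = 0.74)
  tolp <- c(1.5, 1.0, 1.5, 1.0, 1.5, 1.0)
  for (i in seq_along(ref)) {
    got <- tb$error_pct[tb$model == names(ref)[i]]
    rows[[length(rows) + 1]] <- data.frame(
      case = "speed_errors", parameter = names(ref)[i], value = got,
      oracle = unname(ref[i]), rel_error = abs(got - ref[i]),
      tol = tolp[i], pass = abs(got - ref[i]) <= tolp[i])
  }
  do.call(rbind, rows)
}

# Relative magnitude of the entries that must vanish in the
# stroke-averaged helix resistance matrix (all axial-transverse couplings
# and the transverse off-diagonals of the FU and L-Omega blocks).
helix_pattern_residual <- function(M) {
  zero_mask <- matrix(FALSE, 6, 6)
  ax <- c(1, 4); tr <- c(2, 3, 5, 6)
  zero_mask[ax, tr] <- TRUE
  zero_mask[tr, ax] <- TRUE
  zero_mask[2, 3] <- zero_mask[3, 2] <- TRUE   # FU transverse off-diagonal
  zero_mask[5, 6] <- zero_mask[6, 5] <- TRUE   # L-Omega transverse off-diag
  max(abs(M[zero_mask])) / norm(M, "F")
}

# Closed-form slender-helix RFT scalars (uniform helix, whole turns):
# with beta = b k, pitch angle cos(theta) = 1/sqrt(1+beta^2) and contour
# length Lambda = L sqrt(1+beta^2),
#   A = Lambda (C_T cos^2 + C_N sin^2)
#   B = Lambda (C_T - C_N) b sin cos * chirality sign convention
#   C = Lambda b^2 (C_N cos^2 + C_T sin^2)
helix_rft_closed_form <- function(spec, model) {
  beta <- spec$b * spec$k
  c2 <- 1 / (1 + beta^2); s2 <- 1 - c2
  Lam <- spec$L * sqrt(1 + beta^2)
  list(A = Lam * (model$C_T * c2 + model$C_N * s2),
       B = spec$chirality * Lam * (model$C_T - model$C_N) * spec$b *
         sqrt(s2 * c2),
       C = Lam * spec$b^2 * (model$C_N * c2 + model$C_T * s2))
}

#' Write a tabular report
#'
#' CSV output keeps the column order of the input and prints floating
#' point values with 6 significant digits; JSON output is an array of row
#' records.
#'
#' @param rows a data frame.
#' @param path output file.
#' @param format "csv" or "json".
#' @return The path, invisibly.
#' @export
write_report <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (format == "csv") {
    fmt <- rows
    for (j in seq_along(fmt))
      if (is.double(fmt[[j]])) fmt[[j]] <- signif(fmt[[j]], 6)
    utils::write.csv(fmt, path, row.names = FALSE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
}
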