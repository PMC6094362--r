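# Correcting factor, performance measures, and flagellar-length studies.

#' Geometric correcting factor for the additive approximation
#'
#' The additive approximation mis-estimates the swimming speed chiefly
#' because (i) hydrodynamic screening lowers the true assembly drag below
#' the sum of isolated drags and (ii) the head modifies the flagellum's
#' coupling coefficient.  Both effects are captured by the scalar
#' \deqn{upsilon = (A0 + A)(B1 + B2) / ((A1 + A2) B),}
#' built from the isolated scalars (A0 head drag, A and B flagellum drag
#' and coupling) and the coupled-solver partwise sums.  Multiplying the
#' additive-approximation speed by upsilon recovers the coupled prediction
#' to within a few percent; upsilon depends on geometry only (it is
#' invariant under rescaling of mu and omega).
#'
#' @param A0 isolated head drag (6 pi mu R for a sphere).
#' @param A,B isolated flagellum axial drag and coupling scalars (coupled
#'   solver on the flagellum alone, or RFT).
#' @param parts a \code{\link{partwise_resistance}} of the assembly, or a
#'   named vector/list with \code{A1, A2, Bhat1, Bhat2, Bbar1, Bbar2}.
#' @return upsilon (scalar).
#' @export
correction_factor <- function(A0, A, B, parts) {
  sc <- if (inherits(parts, "partwise_resistance")) as.list(parts$scalars)
        else as.list(parts)
  Asum <- sc$A1 + sc$A2
  Bsum <- 0.5 * (sc$Bhat1 + sc$Bhat2 + sc$Bbar1 + sc$Bbar2)
  if (B == 0 || Asum == 0)
    stop("degenerate propeller: zero coupling or zero assembly drag")
  unname((A0 + A) * Bsum / (Asum * B))
}

#' Performance measures of a swim solution
#'
#' Computes the six performance measures in their global, additive and
#' corrected variants:
#' \describe{
#'   \item{eta_en1}{energetic efficiency, useful rate = power to drag the
#'     head alone: \code{A0 U^2 / (T_motor omega)}.}
#'   \item{eta_en2}{energetic efficiency with the whole-swimmer drag:
#'     \code{(A1+A2) U^2 / (T_motor omega)}.}
#'   \item{eta_pr1}{distance per flagellar revolution, \code{U/(omega - Omega)}.}
#'   \item{eta_pr2}{distance per motor revolution, \code{U/omega}.}
#'   \item{eta_sw}{distance per unit work, \code{U/(T_motor omega)}.}
#'   \item{w}{work per distance, \code{T_motor omega / U} (the reciprocal
#'     of eta_sw; reported as Inf when U = 0).}
#' }
#' Global variants use the solved \code{U}, \code{Omega}, \code{T_motor};
#' additive variants are the closed forms in the isolated scalars; the
#' corrected variants rescale the additive ones by \code{upsilon^2} (the
#' energetic pair), \code{upsilon} (the distance measures) and
#' \code{1/upsilon} (w).
#'
#' @param solution a \code{swim_solution} (global variant source).
#' @param A0,C0 head scalars.
#' @param A,B,C isolated flagellum scalars.
#' @param parts \code{\link{partwise_resistance}} (for the whole-swimmer
#'   drag in eta_en2 and for upsilon); may be NULL, in which case the
#'   additive sum A0+A is used and upsilon is taken as 1.
#' @param omega motor rate.
#' @return A data frame of class \code{"efficiency_report"} with one row
#'   per measure and columns \code{global}, \code{additive},
#'   \code{corrected}, plus an \code{upsilon} attribute.
#' @export
efficiencies <- function(solution, A0, C0, A, B, C, parts = NULL,
                         omega = solution$omega) {
  stopifnot(inherits(solution, "swim_solution"))
  A0 <- unname(A0); C0 <- unname(C0)
  A <- unname(A); B <- unname(B); C <- unname(C)
  U <- solution$U; Omega <- solution$Omega; Tm <- solution$T_motor
  if (!is.na(Tm) && Tm <= 0) stop("T_motor must be positive")
  ups <- if (is.null(parts)) 1 else correction_factor(A0, A, B, parts)
  Asum <- if (is.null(parts)) A0 + A else
    sum(parts$scalars[c("A1", "A2")])
  den1 <- (A + A0) * C - B^2
  den2 <- (A + A0) * (C + C0) - B^2
  add <- c(eta_en1 = A0 * C0 * B^2 / (den1 * den2),
           eta_en2 = (A + A0) * C0 * B^2 / (den1 * den2),
           eta_pr1 = B / (A + A0),
           eta_pr2 = C0 * B / den2,
           eta_sw  = B / (den1 * omega),
           w       = den1 * omega / B)
  glob <- c(eta_en1 = A0 * U^2 / (Tm * omega),
            eta_en2 = Asum * U^2 / (Tm * omega),
            eta_pr1 = U / (omega - Omega),
            eta_pr2 = U / omega,
            eta_sw  = U / (Tm * omega),
            w       = if (U == 0) Inf else Tm * omega / U)
  corr <- add * c(ups^2, ups^2, ups, ups, ups, 1 / ups)
  out <- data.frame(measure = names(add), global = unname(glob),
                    additive = unname(add), corrected = unname(corr))
  attr(out, "upsilon") <- ups
  class(out) <- c("efficiency_report", class(out))
  out
}

# ---- Table-style comparison of speed predictions -------------------------

#' Compare swimming-speed predictions across models
#'
#' Runs the full comparison for one assembly: the coupled (global)
#' solution as reference, then the additive approximation, Gray-Hancock
#' RFT and Lighthill RFT, each uncorrected and upsilon-corrected.  For
#' every simplified model, upsilon is built from that model's own isolated
#' scalars (A, B) together with the coupled-solver partwise sums, which is
#' the hybrid recipe that lets a local theory borrow the interaction
#' information from one coupled solve.
#'
#' @param assembly an \code{\link{assembly_spec}}.
#' @param nodes_per_turn,n_head solver resolution.
#' @param n_phase stroke-averaging phase count.
#' @return A data frame with columns \code{model}, \code{U},
#'   \code{error_pct} (relative speed error vs the global solution, in
#'   percent; NA for the reference row).
#' @examples
#' \donttest{
#' asm <- assembly_spec(head_spec(2), filament_spec(1, 8, 2, 1/16))
#' compare_speed_models(asm, nodes_per_turn = 16, n_head = 200)
#' }
#' @export
compare_speed_models <- function(assembly, nodes_per_turn = 32,
                                 n_head = 600, n_phase = 1) {
  stopifnot(inherits(assembly, "assembly_spec"))
  fl <- assembly$filament
  mu <- assembly$mu; omega <- assembly$omega
  hd <- sphere_coefficients(assembly$head$R, mu)

  disc_of <- function(ph) assemble(assembly, nodes_per_turn, n_head, phase = ph)
  parts <- partwise_resistance(if (n_phase > 1) disc_of else disc_of(0),
                               pole = c(0, 0, 0), mu = mu, n_phase = n_phase)
  glob <- solve_global(disc_of(0), omega, mu = mu, parts = parts)

  # isolated flagellum via the coupled solver (about its own axial pole)
  iso_of <- function(ph)
    filament_discretization(fl, nodes_per_turn, ph, x0 = 0)
  iso <- resistance_matrix(if (n_phase > 1) iso_of else iso_of(0),
                           pole = c(fl$L / 2, 0, 0), mu = mu,
                           n_phase = n_phase)
  abc <- axial_coefficients(iso)

  # RFT always acts on the ideal (untapered) helix of the same family
  fl_rft <- if (fl$k_E > 0)
    filament_spec(fl$b, fl$lambda, fl$n_turns, fl$r, 0, fl$chirality,
                  fl$phase) else fl
  gh <- axial_coefficients(filament_resistance_rft(
    fl_rft, drag_coefficients("gray_hancock", fl$lambda, fl$r, mu)))
  lh <- axial_coefficients(filament_resistance_rft(
    fl_rft, drag_coefficients("lighthill", fl$lambda, fl$r, mu)))

  one <- function(abc, tag) {
    sol <- solve_additive(hd$A0, hd$C0, abc["A"], abc["B"], abc["C"],
                          omega, method = tag)
    ups <- correction_factor(hd$A0, abc["A"], abc["B"], parts)
    c(U = sol$U, U_corr = ups * sol$U, upsilon = ups)
  }
  aa <- one(abc, "additive"); rg <- one(gh, "rft-gh"); rl <- one(lh, "rft-lighthill")
  Ug <- glob$U
  err <- function(u) 100 * abs(u - Ug) / abs(Ug)
  data.frame(
    model = c("global", "additive", "additive_corrected",
              "rft_gray_hancock", "rft_gray_hancock_corrected",
              "rft_lighthill", "rft_lighthill_corrected"),
    U = c(Ug, aa["U"], aa["U_corr"], rg["U"], rg["U_corr"],
          rl["U"], rl["U_corr"]),
    error_pct = c(NA, err(aa["U"]), err(aa["U_corr"]), err(rg["U"]),
                  err(rg["U_corr"]), err(rl["U"]), err(rl["U_corr"])),
    row.names = NULL)
}

# ---- Length sweep --------------------------------------------------------

#' Sweep the flagellum length
#'
#' Re-solves the swimming problem over a grid of turn counts at fixed
#' pitch, amplitude, filament radius, head size and motor rate, comparing
#' the global approach, the additive approximation and its corrected
#' variant.  One row per (n_turns, method) with the speed, rotation rate,
#' motor torque, upsilon and all six performance measures, plus the
#' partwise sums used downstream.
#'
#' @param assembly template \code{\link{assembly_spec}} (its filament's
#'   \code{n_turns} is replaced by each grid value).
#' @param n_turns_grid numeric vector of turn counts.
#' @param methods subset of \code{c("global", "additive", "corrected")}.
#' @param nodes_per_turn,n_head,n_phase solver resolution.
#' @return A data frame; failed grid points are dropped with a warning.
#' @export
sweep_lengths <- function(assembly, n_turns_grid,
                          methods = c("global", "additive", "corrected"),
                          nodes_per_turn = 32, n_head = 600, n_phase = 1) {
  stopifnot(inherits(assembly, "assembly_spec"))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(n_turns_grid, function(nt) {
    tryCatch(sweep_point(assembly, nt, methods, nodes_per_turn, n_head,
                         n_phase),
             error = function(e) {
               warning("sweep point n_turns = ", nt, " failed: ",
                       conditionMessage(e))
               NULL
             })
  })
  do.call(rbind, rows)
}

sweep_point <- function(assembly, nt, methods, nodes_per_turn, n_head,
                        n_phase) {
  fl <- assembly$filament
  fl2 <- filament_spec(fl$b, fl$lambda, nt, fl$r, fl$k_E, fl$chirality,
                       fl$phase)
  asm <- assembly_spec(assembly$head, fl2, assembly$gap, assembly$omega,
                       assembly$mu)
  mu <- asm$mu; omega <- asm$omega
  hd <- sphere_coefficients(asm$head$R, mu)
  disc_of <- function(ph) assemble(asm, nodes_per_turn, n_head, phase = ph)
  parts <- partwise_resistance(if (n_phase > 1) disc_of else disc_of(0),
                               mu = mu, n_phase = n_phase)
  glob <- solve_global(disc_of(0), omega, mu = mu, parts = parts)
  iso_of <- function(ph)
    filament_discretization(fl2, nodes_per_turn, ph, x0 = 0)
  iso <- resistance_matrix(if (n_phase > 1) iso_of else iso_of(0),
                           pole = c(fl2$L / 2, 0, 0), mu = mu,
                           n_phase = n_phase)
  abc <- axial_coefficients(iso)
  add <- solve_additive(hd$A0, hd$C0, abc["A"], abc["B"], abc["C"], omega)
  ups <- correction_factor(hd$A0, abc["A"], abc["B"], parts)
  eff <- efficiencies(glob, hd$A0, hd$C0, abc["A"], abc["B"], abc["C"],
                      parts, omega)
  sc <- as.list(parts$scalars)
  base <- data.frame(n_turns = nt, L_over_lambda = nt,
                     A0 = hd$A0, C0 = hd$C0,
                     A_iso = unname(abc["A"]), B_iso = unname(abc["B"]),
                     C_iso = unname(abc["C"]),
                     A_sum = sc$A1 + sc$A2, C_sum = sc$C1 + sc$C2,
                     B_sum = 0.5 * (sc$Bhat1 + sc$Bhat2 + sc$Bbar1 + sc$Bbar2),
                     Bhat2 = sc$Bhat2, upsilon = ups)
  pick <- function(method, U, Omega, Tm, col) {
    cbind(base, data.frame(method = method, U = U, Omega = Omega,
                           T_motor = Tm,
                           eta_en1 = eff[eff$measure == "eta_en1", col],
                           eta_en2 = eff[eff$measure == "eta_en2", col],
                           eta_pr1 = eff[eff$measure == "eta_pr1", col],
                           eta_pr2 = eff[eff$measure == "eta_pr2", col],
                           eta_sw = eff[eff$measure == "eta_sw", col],
                           w = eff[eff$measure == "w", col]))
  }
  out <- NULL
  if ("global" %in% methods)
    out <- rbind(out, pick("global", glob$U, glob$Omega, glob$T_motor,
                           "global"))
  if ("additive" %in% methods)
    out <- rbind(out, pick("additive", add$U, add$Omega, add$T_motor,
                           "additive"))
  if ("corrected" %in% methods)
    out <- rbind(out, pick("corrected", ups * add$U, add$Omega,
                           add$T_motor, "corrected"))
  out
}

# ---- Length optimization -------------------------------------------------

#' Optimal flagellum length for a performance measure
#'
#' Scans a grid of turn counts, then refines with golden-section/Brent
#' search (\code{stats::optimize}) around the best grid point.  If the
#' metric is monotone over the bracket (grid maximum at an endpoint), the
#' endpoint is returned with \code{interior = FALSE}.
#'
#' @param assembly template \code{\link{assembly_spec}}.
#' @param metric one of \code{"speed"}, \code{"eta_en1"},
#'   \code{"eta_en2"}, \code{"eta_pr1"}, \code{"eta_pr2"},
#'   \code{"eta_sw"}; ignored when \code{metric_fn} is given.
#' @param method variant to optimize: "global", "additive" or "corrected".
#' @param bracket interval of turn counts.
#' @param n_grid grid points for the initial scan.
#' @param tol refinement tolerance on n_turns.
#' @param metric_fn optional function(n_turns) -> value, overriding the
#'   built-in metrics (used for testing and custom measures).
#' @param ... resolution arguments passed to \code{\link{sweep_lengths}}.
#' @return List with \code{n_turns}, \code{value}, \code{interior}
#'   (logical), and the scanned \code{grid} data frame.
#' @export
optimize_length <- function(assembly = NULL,
                            metric = c("speed", "eta_en1", "eta_en2",
                                       "eta_pr1", "eta_pr2", "eta_sw"),
                            method = c("global", "additive", "corrected"),
                            bracket = c(1, 20), n_grid = 8, tol = 0.05,
                            metric_fn = NULL, ...) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  if (is.null(metric_fn)) {
    stopifnot(inherits(assembly, "assembly_spec"))
    col <- if (metric == "speed") "U" else metric
    metric_fn <- function(nt) {
      row <- sweep_lengths(assembly, nt, methods = method, ...)
      abs(row[[col]])
    }
  }
  grid_x <- seq(bracket[1], bracket[2], length.out = n_grid)
  grid_y <- vapply(grid_x, metric_fn, numeric(1))
  i <- which.max(grid_y)
  grid <- data.frame(n_turns = grid_x, value = grid_y)
  if (i == 1L || i == n_grid) {
    return(list(n_turns = grid_x[i], value = grid_y[i], interior = FALSE,
                grid = grid))
  }
  opt <- stats::optimize(metric_fn, lower = grid_x[i - 1],
                         upper = grid_x[i + 1], maximum = TRUE, tol = tol)
  list(n_turns = opt$maximum, value = opt$objective, interior = TRUE,
       grid = grid)
}
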