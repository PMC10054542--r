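#' @title Rigid-body sampling and relaxation
#' @name sampling
#' @description
#' Rigid-body Metropolis Monte Carlo of a particle system in any
#' implicit membrane: each step draws a uniform translation within
#' +/- max_translation per axis plus a rotation about a random axis
#' through the centroid by a uniform angle within +/- max_rotation,
#' accepted with probability \eqn{\min(1, e^{-\Delta E / k_B T})}.
#' Gradient relaxation moves the system rigidly along the net membrane
#' force until the energy change falls below tolerance.
NULL

# Boltzmann constant, kcal mol^-1 K^-1
KB_KCAL <- 0.0019872

#' Rigid-body Metropolis Monte Carlo insertion
#'
#' @param ps a \code{particle_system} with \code{sasa} and \code{etr}
#' @param membrane a \code{membrane} object
#' @param temperature temperature in Kelvin (default 300)
#' @param steps number of MC steps
#' @param max_translation maximum per-axis translation per move (A)
#' @param max_rotation maximum rotation per move (degrees)
#' @param seed integer RNG seed; identical seeds give bitwise identical
#'   trajectories
#' @param vector_pair optional particle-id pair for tilt tracking
#' @param record_every record every k-th step (default 1)
#' @param max_depth half-height of the simulation box (Angstrom):
#'   moves taking the centroid beyond this signed depth are rejected,
#'   emulating the finite box of an insertion simulation (default Inf,
#'   no wall)
#' @return a \code{trajectory}: data frame (step, depth, tilt, e_int,
#'   e_lip, e_imp, accepted) with the final system, seed and move
#'   parameters as attributes
#' @export
run_monte_carlo <- function(ps, membrane, temperature = 300,
                            steps = 1000, max_translation = 1,
                            max_rotation = 5, seed = 1,
                            vector_pair = NULL, record_every = 1L,
                            max_depth = Inf) {
  stopifnot(temperature > 0, steps >= 1)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed)
  kT <- KB_KCAL * temperature
  e <- total_energy(ps, membrane)
  if (!is.finite(e$e_imp)) stop("non-finite starting energy")
  n_rec <- length(seq(1L, steps, by = record_every))
  rec <- data.frame(step = integer(n_rec), depth = numeric(n_rec),
                    tilt = numeric(n_rec), e_int = numeric(n_rec),
                    e_lip = numeric(n_rec), e_imp = numeric(n_rec),
                    accepted = logical(n_rec))
  ri <- 0L
  for (s in seq_len(steps)) {
    shift <- stats::runif(3, -max_translation, max_translation)
    axis <- stats::rnorm(3)
    angle <- stats::runif(1, -max_rotation, max_rotation)
    cand <- ps_translate(ps_rotate(ps, rotation_matrix(axis, angle)),
                         shift)
    e_cand <- total_energy(cand, membrane)
    if (!is.finite(e_cand$e_imp)) {
      stop(sprintf("non-finite energy at step %d; pose centroid (%.2f, %.2f, %.2f)",
                   s, ps_center(cand)[1], ps_center(cand)[2],
                   ps_center(cand)[3]))
    }
    dE <- e_cand$e_imp - e$e_imp
    in_box <- is.infinite(max_depth) ||
      abs(membrane_depth(membrane,
                         matrix(ps_center(cand), 1, 3))$z) <= max_depth
    accepted <- in_box && (dE <= 0 || stats::runif(1) < exp(-dE / kT))
    if (accepted) { ps <- cand; e <- e_cand }
    if ((s - 1L) %% record_every == 0L) {
      ri <- ri + 1L
      com <- ps_center(ps)
      d <- membrane_depth(membrane, matrix(com, 1, 3))
      tilt <- NA_real_
      if (!is.null(vector_pair)) {
        tilt <- insertion_metrics(ps, membrane, vector_pair)$tilt
      }
      rec[ri, ] <- list(s, d$z, tilt, e$e_int, e$e_lip, e$e_imp,
                        accepted)
    }
  }
  structure(rec, class = c("trajectory", "data.frame"),
            final = ps, seed = seed,
            parameters = list(temperature = temperature, steps = steps,
                              max_translation = max_translation,
                              max_rotation = max_rotation,
                              record_every = record_every))
}

#' @export
print.trajectory <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf("MC trajectory: %d recorded steps, T = %g K, acceptance %.1f%%\n",
              nrow(x), p$temperature, 100 * mean(x$accepted)))
  invisible(x)
}

#' Final particle system of a trajectory
#' @param traj a \code{trajectory}
#' @return the \code{particle_system} at the last step
#' @export
trajectory_final <- function(traj) attr(traj, "final")

#' Rigid gradient relaxation in the membrane
#'
#' Steepest descent on the rigid-body pose: the system is translated
#' along the net membrane force; when a step raises the energy it is
#' rejected and the step size halved.  With \code{enm} given, membrane
#' and spring forces act per particle instead (flexible relaxation).
#'
#' @param ps a \code{particle_system}
#' @param membrane a \code{membrane} object
#' @param step_size initial step (Angstrom, default 0.5)
#' @param max_iter iteration cap
#' @param tol stop when |energy change| < tol (kcal/mol)
#' @param enm optional \code{elastic_network} for flexible relaxation
#' @return list with the relaxed \code{system}, final \code{energy}
#'   breakdown, \code{iterations} used and \code{converged} flag
#' @export
minimize <- function(ps, membrane, step_size = 0.5, max_iter = 500,
                     tol = 1e-6, enm = NULL) {
  e <- total_energy(ps, membrane)$e_imp
  if (!is.null(enm)) e <- e + enm_energy(enm, ps_coords(ps))
  h <- step_size
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- energy_gradient(ps, membrane)
    if (!is.null(enm)) {
      f <- f + enm_forces(enm, ps_coords(ps))
      fn <- sqrt(max(rowSums(f^2)))
      if (fn < 1e-12) { converged <- TRUE; break }
      cand <- ps_set_coords(ps, ps_coords(ps) + f / fn * h)
    } else {
      fnet <- colSums(f)
      fn <- sqrt(sum(fnet^2))
      if (fn < 1e-12) { converged <- TRUE; break }
      cand <- ps_translate(ps, fnet / fn * h)
    }
    e_cand <- total_energy(cand, membrane)$e_imp
    if (!is.null(enm)) e_cand <- e_cand + enm_energy(enm, ps_coords(cand))
    if (e_cand < e) {
      if (abs(e - e_cand) < tol) {
        ps <- cand; e <- e_cand; converged <- TRUE; break
      }
      ps <- cand; e <- e_cand
    } else {
      h <- h / 2  # overshoot: halve and retry
      if (h < 1e-9) { converged <- TRUE; break }
    }
  }
  list(system = ps, energy = total_energy(ps, membrane),
       iterations = iter, converged = converged)
}
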