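#' Converge the SCFT equations to a (meta)stable configuration
#'
#' Fixed-point iteration on the self-consistency conditions
#' `w_A = chiN phi_B`, `w_B = chiN phi_A` with the pressure field adjusted
#' so that `phi_tail + phi_head + phi_solvent = 1` holds exactly at the
#' fixed point (the local density excess is pushed back with strength
#' `params$kappa_incomp` during iteration; no penalty term remains at
#' convergence).  Iterations start with damped simple (Picard) mixing and
#' switch to Anderson acceleration, monitoring the max-norm field residual.
#'
#' For grids with a `"reservoir"` boundary the outermost-cell fields are
#' pinned to the homogeneous bulk-solvent values at the current `mu`,
#' emulating the connection to a lipid reservoir.
#'
#' @param init initial [field_state()] (typically from [seed_topology()]).
#' @param params an [scft_params()] object.
#' @param grid an [make_grid()] object.
#' @param tol convergence tolerance on the max-norm field residual.
#' @param max_iter iteration budget.
#' @param lambda damping of the simple-mixing warm-up.
#' @param n_warmup number of simple-mixing iterations before Anderson
#'   acceleration starts.
#' @param anderson_m Anderson history depth.
#' @param beta Anderson damping.
#' @param on_max_iter `"error"` (default) raises a classed error carrying
#'   the last residual; `"warn"` returns the unconverged state with a
#'   warning.
#' @param history_every record the residual history every this many
#'   iterations.
#'
#' @return An object of class `scft_state`: `fields`, `dens`,
#'   `free_energy`, `excess_free_energy`, `residual_history` (data frame
#'   with `iter`, `residual`, `free_energy`), `converged`, `iterations`,
#'   `params`, `grid`.
#' @export
scft_converge <- function(init, params, grid, tol = 1e-6, max_iter = 2000,
                          lambda = 0.05, n_warmup = 100, anderson_m = 10,
                          beta = 0.5, on_max_iter = c("error", "warn"),
                          history_every = 1L) {
  stopifnot(inherits(init, "scft_fields"), inherits(params, "scft_params"),
            inherits(grid, "scft_grid"))
  on_max_iter <- match.arg(on_max_iter)
  npts <- grid$npts
  chiN <- params$chiN
  cp <- params$kappa_incomp

  pin <- pinned_idx(grid)
  bulk <- if (length(pin)) solve_homogeneous(params, "solvent") else NULL

  x <- c(init$w_A + init$xi, init$w_B + init$xi)
  if (length(pin)) {
    x[pin] <- bulk$W_A
    x[pin + npts] <- bulk$W_B
  }

  evaluate <- function(x) scft_map(x, params, grid, pin, bulk)

  hist_iter <- integer(0); hist_res <- numeric(0); hist_F <- numeric(0)
  X_hist <- NULL; F_hist <- NULL
  best_res <- Inf
  converged <- FALSE
  ev <- NULL
  res <- NA_real_
  grow_count <- 0L

  for (it in 0:max_iter) {
    ev <- evaluate(x)
    Rv <- ev$g - x
    res <- max(abs(Rv))
    if (it %% history_every == 0L || res < tol) {
      hist_iter <- c(hist_iter, it)
      hist_res <- c(hist_res, res)
      hist_F <- c(hist_F, ev$energy)
    }
    if (!is.finite(res))
      stop(structure(class = c("scft_divergence", "error", "condition"),
                     list(message = sprintf(
                       "SCFT iteration diverged (non-finite residual at iteration %d)", it),
                       call = sys.call(-1), iteration = it)))
    if (res < tol) { converged <- TRUE; break }
    if (res < best_res) { best_res <- res; grow_count <- 0L } else {
      grow_count <- grow_count + 1L
      if (grow_count > 200L && res > 1e3 * best_res)
        stop(structure(class = c("scft_divergence", "error", "condition"),
                       list(message = sprintf(
                         "SCFT iteration diverging: residual %.3e (best %.3e) at iteration %d",
                         res, best_res, it), call = sys.call(-1),
                         iteration = it, residual = res)))
    }

    if (it >= n_warmup && res > 5 * best_res && !is.null(X_hist)) {
      # Anderson step overshot: flush the history and damp back down
      X_hist <- F_hist <- NULL
    }
    if (it < n_warmup || anderson_m < 1 ||
        (is.null(X_hist) && res > 5 * best_res)) {
      x_new <- x + lambda * Rv
    } else {
      # Anderson acceleration (type II) on the stacked field vector
      X_hist <- cbind(X_hist, x); F_hist <- cbind(F_hist, Rv)
      k <- ncol(X_hist)
      if (k > anderson_m + 1L) {
        X_hist <- X_hist[, -1L, drop = FALSE]
        F_hist <- F_hist[, -1L, drop = FALSE]
        k <- ncol(X_hist)
      }
      if (k == 1L) {
        x_new <- x + lambda * Rv
      } else {
        dF <- F_hist[, -1L, drop = FALSE] - F_hist[, -k, drop = FALSE]
        dX <- X_hist[, -1L, drop = FALSE] - X_hist[, -k, drop = FALSE]
        A <- crossprod(dF)
        gamma <- tryCatch(
          solve(A + 1e-12 * max(diag(A), 1e-300) * diag(ncol(A)),
                crossprod(dF, Rv)),
          error = function(e) NULL)
        if (is.null(gamma)) {
          x_new <- x + lambda * Rv
          X_hist <- F_hist <- NULL
        } else {
          x_new <- x + beta * Rv - (dX + beta * dF) %*% gamma
          x_new <- as.numeric(x_new)
        }
      }
    }
    if (length(pin)) {
      x_new[pin] <- bulk$W_A
      x_new[pin + npts] <- bulk$W_B
    }
    x <- x_new
  }

  if (!converged) {
    msg <- sprintf("SCFT did not converge in %d iterations (residual %.3e)",
                   max_iter, res)
    if (on_max_iter == "error")
      stop(structure(class = c("scft_max_iter", "error", "condition"),
                     list(message = msg, call = sys.call(-1),
                          residual = res, iterations = max_iter)))
    warning(msg)
  }

  W_A <- x[seq_len(npts)]; W_B <- x[npts + seq_len(npts)]
  xi <- (W_A + W_B - chiN) / 2
  fields <- field_state(W_A - xi, W_B - xi, xi, grid)
  omega_b <- solve_homogeneous(params, "solvent")$omega
  structure(list(fields = fields, dens = ev$dens, free_energy = ev$energy,
                 excess_free_energy = ev$energy - omega_b * grid$volume,
                 residual_history = data.frame(iter = hist_iter,
                                               residual = hist_res,
                                               free_energy = hist_F),
                 converged = converged, iterations = it,
                 incompressibility = ev$incomp,
                 params = params, grid = grid),
            class = "scft_state")
}

# generic Anderson-accelerated fixed-point solver for x = map(x); used by
# the constrained (inverse) SCFT solves of the string method.  Returns the
# final iterate, the residual max-norm, and whether tol was met.
anderson_solve <- function(map, x0, tol = 1e-6, max_iter = 200, m = 10,
                           beta = 0.7, lambda = 0.3, n_warmup = 5) {
  x <- x0
  X_hist <- F_hist <- NULL
  best <- Inf
  x_best <- x0
  res <- NA_real_
  for (it in 0:max_iter) {
    gx <- map(x)
    Rv <- gx - x
    res <- max(abs(Rv))
    if (!is.finite(res)) stop("anderson_solve: non-finite residual")
    if (res < tol) return(list(x = x, residual = res, converged = TRUE))
    if (res > 5 * best) X_hist <- F_hist <- NULL
    if (res < best) { best <- res; x_best <- x }
    if (it < n_warmup) {
      x <- x + lambda * Rv
      next
    }
    X_hist <- cbind(X_hist, x); F_hist <- cbind(F_hist, Rv)
    k <- ncol(X_hist)
    if (k > m + 1L) {
      X_hist <- X_hist[, -1L, drop = FALSE]
      F_hist <- F_hist[, -1L, drop = FALSE]
      k <- k - 1L
    }
    if (k == 1L) {
      x <- x + lambda * Rv
    } else {
      dF <- F_hist[, -1L, drop = FALSE] - F_hist[, -k, drop = FALSE]
      dX <- X_hist[, -1L, drop = FALSE] - X_hist[, -k, drop = FALSE]
      A <- crossprod(dF)
      gamma <- tryCatch(
        solve(A + 1e-12 * max(diag(A), 1e-300) * diag(ncol(A)),
              crossprod(dF, Rv)),
        error = function(e) NULL)
      x <- if (is.null(gamma)) x + lambda * Rv else
        as.numeric(x + beta * Rv - (dX + beta * dF) %*% gamma)
    }
  }
  # not converged: return the best iterate seen
  list(x = x_best, residual = best, converged = FALSE)
}

# one application of the SCFT fixed-point map on the stacked propagation
# fields x = c(W_A, W_B): computes densities, the self-consistency targets
# (with the pressure estimate and the incompressibility drive), and the
# free energy; pinned cells are overwritten with bulk values
scft_map <- function(x, params, grid, pin = integer(0), bulk = NULL) {
  npts <- grid$npts
  chiN <- params$chiN
  cp <- params$kappa_incomp
  W_A <- x[seq_len(npts)]; W_B <- x[npts + seq_len(npts)]
  fs <- field_state(W_A, W_B, 0, grid)
  props <- propagate(fs, grid, params)
  dens <- compute_densities(props, fs, params, grid)
  # cap the density overshoots entering the targets: physical volume
  # fractions never exceed 1, so the fixed point is unaffected, but far
  # from it the exp(mu)-amplified excursions would destabilize the map
  phi_A <- pmin(dens$phi_tail, 2)
  phi_B <- pmin(dens$phi_head + dens$phi_solvent, 2)
  delta <- pmin(pmax(phi_A + phi_B - 1, -0.5), 0.5)
  xi_est <- (W_A + W_B - chiN) / 2
  tA <- chiN * phi_B + xi_est + cp * delta
  tB <- chiN * phi_A + xi_est + cp * delta
  if (length(pin)) {
    tA[pin] <- bulk$W_A
    tB[pin] <- bulk$W_B
  }
  list(g = c(tA, tB), dens = dens, fields = fs,
       energy = grand_free_energy(fs, dens, params, grid),
       incomp = max(abs(dens$phi_tail + dens$phi_head +
                        dens$phi_solvent - 1)))
}

# indices of field cells pinned to bulk for reservoir boundaries
pinned_idx <- function(grid) {
  if (!identical(grid$boundary, "reservoir")) return(integer(0))
  switch(grid$kind,
    planar1d = c(1L, grid$dims),
    radial1d = grid$dims,
    axisym2d = {
      nr <- grid$dims[1]; nz <- grid$dims[2]
      nr * (seq_len(nz) - 1L) + nr   # outermost radial cell of every z row
    },
    integer(0))
}

#' @export
print.scft_state <- function(x, ...) {
  cat(sprintf("SCFT state on %s grid: %s, F = %.6f kT, excess = %.6f kT\n",
              x$grid$kind,
              if (x$converged) "converged" else "NOT converged",
              x$free_energy, x$excess_free_energy))
  cat(sprintf("  incompressibility residual %.2e, mu = %g\n",
              x$incompressibility, x$params$mu))
  invisible(x)
}
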