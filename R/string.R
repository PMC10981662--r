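#' String of configurations between two membrane states
#'
#' A string path is an ordered set of `M` node configurations connecting
#' two endpoint states, together with the metric used to measure arc
#' length: the root-mean-squared change in local density,
#' \deqn{d(a, b) = \sqrt{\sum_{species} \int (\phi_a - \phi_b)^2 dV / V}.}
#' Nodes live in a linear space (numeric vectors or matrices); each node
#' may carry a separate metric representation (for SCFT strings the node is
#' the field configuration and the metric representation is its density
#' matrix).
#'
#' @param nodes list of node configurations (numeric, all the same shape).
#' @param grid optional [make_grid()] supplying quadrature weights for the
#'   metric; without it all degrees of freedom have unit weight.
#' @param metric_nodes optional list of metric representations (defaults
#'   to the nodes themselves).
#' @return An object of class `string_path` with elements `nodes`,
#'   `metric`, `weights`, `volume`, and `alpha` (normalized cumulative arc
#'   length).
#' @export
string_path <- function(nodes, grid = NULL, metric_nodes = NULL) {
  stopifnot(is.list(nodes), length(nodes) >= 2)
  if (is.null(metric_nodes)) metric_nodes <- nodes
  stopifnot(length(metric_nodes) == length(nodes))
  k <- length(metric_nodes[[1]])
  if (is.null(grid)) {
    weights <- rep(1, k); volume <- k
  } else {
    nrep <- k / grid$npts
    if (nrep != round(nrep)) stop("metric node shape does not match grid")
    weights <- rep(grid$weights, nrep)
    volume <- grid$volume
  }
  p <- structure(list(nodes = nodes, metric = metric_nodes,
                      weights = weights, volume = volume, alpha = NULL),
                 class = "string_path")
  p$alpha <- path_alpha(p)
  p
}

metric_dist <- function(a, b, weights, volume) {
  sqrt(sum(weights * (as.numeric(a) - as.numeric(b))^2) / volume)
}

#' Root-mean-squared density distance between two states
#'
#' The string-method metric: RMS change in local density, summed over the
#' three species and volume-averaged.  Symmetric, zero iff the densities
#' are equal.
#'
#' @param a,b [density_state()] objects on the same grid.
#' @param grid an [make_grid()] object.
#' @return A scalar distance.
#' @export
density_distance <- function(a, b, grid) {
  stopifnot(inherits(a, "scft_density"), inherits(b, "scft_density"))
  if (!identical(dim(density_matrix(a)), dim(density_matrix(b))) ||
      length(a$phi_tail) != grid$npts)
    stop("grid mismatch between density states")
  metric_dist(density_matrix(a), density_matrix(b),
              rep(grid$weights, 3), grid$volume)
}

# adjacent-node distances and normalized cumulative arc length
path_segments <- function(path) {
  M <- length(path$nodes)
  vapply(seq_len(M - 1L), function(m)
    metric_dist(path$metric[[m]], path$metric[[m + 1L]], path$weights,
                path$volume), numeric(1))
}

path_alpha <- function(path) {
  seg <- path_segments(path)
  tot <- sum(seg)
  if (tot == 0) return(seq(0, 1, length.out = length(path$nodes)))
  c(0, cumsum(seg)) / tot
}

#' Redistribute string nodes to equal arc length
#'
#' Piecewise-linear interpolation of the nodes (and their metric
#' representations, with the same interpolation weights) so that adjacent
#' nodes are equidistant in the density metric; the endpoints are
#' untouched.  The redistribution is iterated until the coefficient of
#' variation of the adjacent-node distances drops below `cv_tol` (the
#' interpolated nodes redefine the polyline, so a single pass leaves a
#' residual on strongly curved paths).  Optionally changes the number of
#' nodes.
#'
#' @param path an [string_path()].
#' @param n_nodes number of nodes of the returned path (default:
#'   unchanged).
#' @param cv_tol target coefficient of variation of adjacent distances.
#' @param max_passes iteration cap on the redistribution passes.
#' @return A reparametrized `string_path`.
#' @export
reparametrize <- function(path, n_nodes = length(path$nodes),
                          cv_tol = 1e-8, max_passes = 100) {
  stopifnot(inherits(path, "string_path"), n_nodes >= 2)
  if (sum(path_segments(path)) == 0) stop("degenerate (zero-length) path")
  out <- path
  for (pass in seq_len(max_passes)) {
    seg <- path_segments(out)
    if (length(seg) == n_nodes - 1L && n_nodes > 2L) {
      cv <- stats::sd(seg) / mean(seg)
      if (is.finite(cv) && cv < cv_tol) break
    }
    out <- redistribute_once(out, n_nodes)
    if (n_nodes == 2L) break
  }
  out$alpha <- path_alpha(out)
  out
}

# one pass of piecewise-linear equal-arc-length redistribution
redistribute_once <- function(path, n_nodes) {
  M <- length(path$nodes)
  seg <- path_segments(path)
  tot <- sum(seg)
  s_old <- c(0, cumsum(seg))
  s_new <- seq(0, tot, length.out = n_nodes)
  interp_one <- function(items, m, frac)
    (1 - frac) * items[[m]] + frac * items[[m + 1L]]
  nodes <- vector("list", n_nodes)
  metric <- vector("list", n_nodes)
  nodes[[1]] <- path$nodes[[1]]; metric[[1]] <- path$metric[[1]]
  nodes[[n_nodes]] <- path$nodes[[M]]; metric[[n_nodes]] <- path$metric[[M]]
  if (n_nodes > 2L) for (j in seq(2, n_nodes - 1L)) {
    m <- findInterval(s_new[j], s_old, rightmost.closed = TRUE)
    m <- min(max(m, 1L), M - 1L)
    frac <- if (seg[m] > 0) (s_new[j] - s_old[m]) / seg[m] else 0
    nodes[[j]] <- interp_one(path$nodes, m, frac)
    metric[[j]] <- interp_one(path$metric, m, frac)
  }
  out <- path
  out$nodes <- nodes
  out$metric <- metric
  out
}

#' Free-energy profile along a string
#'
#' @param alpha reaction coordinate values (normalized cumulative RMS
#'   density change).
#' @param F free energies (kT) at each node.
#' @param kappa optional bending rigidity (kT) used to add `F_over_kappa`.
#' @return An object of class `energy_profile` with `alpha`, `F`,
#'   optionally `F_over_kappa`, and the interior minima/maxima indices.
#' @export
energy_profile <- function(alpha, F, kappa = NULL) {
  stopifnot(length(alpha) == length(F), !is.unsorted(alpha))
  n <- length(F)
  interior <- if (n >= 3) 2:(n - 1) else integer(0)
  is_max <- vapply(interior, function(i)
    F[i] > F[i - 1] && F[i] >= F[i + 1], logical(1))
  is_min <- vapply(interior, function(i)
    F[i] < F[i - 1] && F[i] <= F[i + 1], logical(1))
  structure(list(alpha = alpha, F = F,
                 F_over_kappa = if (!is.null(kappa)) F / kappa,
                 kappa = kappa,
                 maxima = interior[is_max], minima = interior[is_min]),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("Energy profile: %d nodes, F range [%.4g, %.4g] kT, %d barrier(s)\n",
              length(x$alpha), min(x$F), max(x$F), length(x$maxima)))
  invisible(x)
}

#' Barriers and metastable states of an energy profile
#'
#' Pairs every interior maximum with the lowest point since the previous
#' interior maximum (or the initial state), giving the forward barrier
#' heights; a monotone profile yields an empty list.  Constant shifts of
#' the profile leave the barriers unchanged.
#'
#' @param profile an [energy_profile()] sampled on at least 5 nodes.
#' @return A data frame with `alpha_peak`, `F_peak`, `alpha_min`, `F_min`,
#'   `dF_forward`; the rate-limiting barrier height is attached as
#'   attribute `"rate_limiting"`.
#' @export
extract_barriers <- function(profile) {
  stopifnot(inherits(profile, "energy_profile"))
  if (length(profile$alpha) < 5)
    stop("profile must be sampled on at least 5 nodes")
  a <- profile$alpha; F <- profile$F
  peaks <- profile$maxima
  if (length(peaks) == 0L) {
    out <- data.frame(alpha_peak = numeric(0), F_peak = numeric(0),
                      alpha_min = numeric(0), F_min = numeric(0),
                      dF_forward = numeric(0))
    attr(out, "rate_limiting") <- 0
    return(out)
  }
  prev <- c(1L, peaks[-length(peaks)])
  rows <- lapply(seq_along(peaks), function(k) {
    seg <- prev[k]:peaks[k]
    im <- seg[which.min(F[seg])]
    data.frame(alpha_peak = a[peaks[k]], F_peak = F[peaks[k]],
               alpha_min = a[im], F_min = F[im],
               dF_forward = F[peaks[k]] - F[im])
  })
  out <- do.call(rbind, rows)
  attr(out, "rate_limiting") <- max(out$dF_forward)
  out
}

#' Relax a string to the minimum free-energy path (generic machinery)
#'
#' Simplified string method: alternate (i) `inner_steps` of free-energy
#' descent on every interior node and (ii) equal-arc-length
#' reparametrization, until the maximal node displacement per sweep (in
#' the density metric) falls below `tol` or `n_outer` sweeps are done.
#' The endpoints are held fixed.
#'
#' @param path an [string_path()] whose endpoints are (independently
#'   converged) stable states.
#' @param relax_fun `function(node, steps)` performing `steps` descent
#'   steps and returning `list(node, metric, energy)`; called with
#'   `steps = 0` to evaluate the fixed endpoints.
#' @param n_outer maximal number of outer sweeps.
#' @param inner_steps descent steps per node per sweep.
#' @param tol convergence threshold on the per-sweep max node displacement.
#' @return A list with the relaxed `path`, the [energy_profile()]
#'   `profile`, the per-sweep displacement history `displacement`, and
#'   `converged`.
#' @export
string_relax <- function(path, relax_fun, n_outer = 100, inner_steps = 10,
                         tol = 1e-4) {
  stopifnot(inherits(path, "string_path"))
  M <- length(path$nodes)
  energies <- numeric(M)
  for (m in c(1L, M)) {
    ev <- relax_fun(path$nodes[[m]], 0L)
    path$metric[[m]] <- ev$metric
    energies[m] <- ev$energy
  }
  disp_hist <- numeric(0)
  converged <- FALSE
  for (sweep in seq_len(n_outer)) {
    old_metric <- path$metric
    for (m in seq(2L, M - 1L)) {
      ev <- relax_fun(path$nodes[[m]], inner_steps)
      if (!all(is.finite(ev$node)))
        stop(sprintf("string node blow-up at alpha = %.3f", path$alpha[m]))
      path$nodes[[m]] <- ev$node
      path$metric[[m]] <- ev$metric
      energies[m] <- ev$energy
    }
    path <- reparametrize(path)
    disp <- max(vapply(seq_len(M), function(m)
      metric_dist(old_metric[[m]], path$metric[[m]], path$weights,
                  path$volume), numeric(1)))
    disp_hist <- c(disp_hist, disp)
    if (disp < tol) { converged <- TRUE; break }
  }
  # energies of the final (reparametrized) nodes
  for (m in seq(2L, M - 1L)) {
    ev <- relax_fun(path$nodes[[m]], 0L)
    path$metric[[m]] <- ev$metric
    energies[m] <- ev$energy
  }
  path$alpha <- path_alpha(path)
  list(path = path, profile = energy_profile(path$alpha, energies),
       displacement = disp_hist, converged = converged)
}

#' Relax an SCFT string to the minimum free-energy path
#'
#' String-method driver for SCFT configurations.  Nodes are density
#' configurations (the free energy of the inhomogeneous mixture is a
#' well-defined functional of the densities; the conjugate fields are a
#' saddle point and cannot be descended directly).  Each descent step
#' (i) inverse-solves the constrained SCFT problem — iterating the fields
#' until the chain statistics reproduce the node's densities — and
#' (ii) moves the node down the thermodynamic force
#' `(chiN (phi_B - phi_A) - (W_A - W_B)) / 2`, the exchange component of
#' `dF/dphi`, which conserves the total density pointwise.  Sweeps
#' alternate with equal-arc-length reparametrization in the RMS density
#' metric (simplified string method); endpoints stay fixed.  Reported free
#' energies are excess grand potentials relative to bulk solvent.
#'
#' @param endpoints list of two converged `scft_state` endpoints.
#' @param params an [scft_params()] object.
#' @param grid an [make_grid()] object.
#' @param M number of string nodes.
#' @param n_outer,inner_steps,tol see [string_relax()].
#' @param dt descent step for the density update.
#' @param n_inverse field-iteration count of each constrained
#'   (inverse) solve.
#' @param eta_inverse damping of the inverse field iteration.
#' @param kappa optional bending rigidity (kT) for the profile's
#'   `F_over_kappa`.
#' @return As [string_relax()], with the profile in kT (and optionally
#'   units of `kappa`).
#' @export
relax_string <- function(endpoints, params, grid, M = 20, n_outer = 60,
                         inner_steps = 2, tol = 1e-4, dt = 0.1,
                         n_inverse = 60, eta_inverse = 2, kappa = NULL) {
  stopifnot(length(endpoints) == 2,
            inherits(endpoints[[1]], "scft_state"),
            inherits(endpoints[[2]], "scft_state"))
  npts <- grid$npts
  omega_b <- solve_homogeneous(params, "solvent")$omega
  chiN <- params$chiN

  gen_dens <- function(W) {
    W <- pmin(pmax(W, -100), 300)
    fs <- field_state(W[seq_len(npts)], W[npts + seq_len(npts)], 0, grid)
    props <- propagate(fs, grid, params)
    list(dens = compute_densities(props, fs, params, grid), fields = fs)
  }

  # solve the constrained problem: fields whose chain statistics generate
  # the node's densities (Anderson-accelerated fixed point)
  inverse_solve <- function(W, phiA_t, phiB_t, iters, tol = 1e-5) {
    imap <- function(W) {
      ev <- gen_dens(W)
      gA <- ev$dens$phi_tail
      gB <- ev$dens$phi_head + ev$dens$phi_solvent
      # clamp: keeps Anderson extrapolation overshoots recoverable
      pmin(pmax(c(W[seq_len(npts)] + eta_inverse * (gA - phiA_t),
                  W[npts + seq_len(npts)] + eta_inverse * (gB - phiB_t)),
                -100), 300)
    }
    sol <- anderson_solve(imap, W, tol = tol * eta_inverse,
                          max_iter = iters)
    Wb <- pmin(pmax(sol$x, -100), 300)
    list(W = Wb, ev = gen_dens(Wb),
         residual = sol$residual / eta_inverse)
  }

  node_energy <- function(phi, W, ev) {
    # -e^mu V Q_l - (1/alpha) V Q_s via the generated-density identities,
    # interaction and field terms on the node (constrained) densities
    lip <- integrate_field(ev$dens$phi_tail + ev$dens$phi_head, grid)
    sol <- integrate_field(ev$dens$phi_solvent, grid) / params$solvent_ratio
    phiA <- phi[, 1]; phiB <- phi[, 2] + phi[, 3]
    inter <- integrate_field(chiN * phiA * phiB -
                             W[seq_len(npts)] * phiA -
                             W[npts + seq_len(npts)] * phiB, grid)
    -lip - sol + inter - omega_b * grid$volume
  }

  pack <- function(phi, W) c(as.vector(phi), W)
  unpack <- function(node) list(phi = matrix(node[seq_len(3 * npts)],
                                             npts, 3),
                                W = node[3 * npts + seq_len(2 * npts)])

  relax_fun <- function(node, steps) {
    u <- unpack(node)
    phi <- u$phi; W <- u$W
    if (steps > 0) for (k in seq_len(steps)) {
      phiA <- phi[, 1]; phiB <- phi[, 2] + phi[, 3]
      inv <- inverse_solve(W, phiA, phiB, n_inverse)
      if (inv$residual > 0.02)
        inv <- inverse_solve(inv$W, phiA, phiB, 3L * n_inverse)
      if (inv$residual > 0.02) next  # constrained solve too loose to move
      W <- inv$W
      f_ex <- (chiN * (phiB - phiA) -
               (W[seq_len(npts)] - W[npts + seq_len(npts)])) / 2
      # trust-region step: never move any density by more than dt
      dt_eff <- dt / max(1, max(abs(f_ex)))
      phiA <- pmin(pmax(phiA - dt_eff * f_ex, 1e-12), 1 - 1e-12)
      phiB <- 1 - phiA
      # head/solvent split follows the chain statistics
      gh <- inv$ev$dens$phi_head; gs <- inv$ev$dens$phi_solvent
      frac <- ifelse(gh + gs > 0, gh / (gh + gs), 0)
      phi <- cbind(phiA, phiB * frac, phiB * (1 - frac))
    }
    inv <- inverse_solve(W, phi[, 1], phi[, 2] + phi[, 3], n_inverse)
    list(node = pack(phi, inv$W), metric = phi,
         energy = node_energy(phi, inv$W, inv$ev))
  }

  mk_node <- function(st) pack(density_matrix(st$dens),
                               c(st$fields$w_A + st$fields$xi,
                                 st$fields$w_B + st$fields$xi))
  x0 <- mk_node(endpoints[[1]]); x1 <- mk_node(endpoints[[2]])
  fracs <- seq(0, 1, length.out = M)
  nodes <- lapply(fracs, function(fr) (1 - fr) * x0 + fr * x1)
  metric <- lapply(nodes, function(nd) unpack(nd)$phi)
  path <- string_path(nodes, grid = NULL, metric_nodes = metric)
  path$weights <- rep(grid$weights, 3)
  path$volume <- grid$volume
  path$alpha <- path_alpha(path)

  res <- string_relax(path, relax_fun, n_outer = n_outer,
                      inner_steps = inner_steps, tol = tol)
  if (!is.null(kappa))
    res$profile <- energy_profile(res$profile$alpha, res$profile$F, kappa)
  res
}
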