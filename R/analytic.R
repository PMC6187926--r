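# Closed-form solutions and independent oracles used to validate the 3D
# finite-volume solvers.  Nothing here touches the 3D code path.

#' Constant-rate sphere model
#'
#' Parameters of the classical steady diffusion problem in a sphere with a
#' spatially uniform (zeroth-order) volumetric sink: radius, rate, tissue
#' diffusivity, surface concentration and the hypoxia threshold.
#'
#' @param Rs spheroid radius, m.
#' @param A constant volumetric consumption rate, mol/(m^3 s).
#' @param D diffusion coefficient in the tissue, m^2/s.
#' @param c_surface concentration at the sphere surface, mol/m^3.
#' @param c_threshold hypoxia threshold concentration, mol/m^3.
#' @return an object of class `sphere_model`.
#' @export
sphere_model <- function(Rs, A, D, c_surface,
                         c_threshold = HYPOXIA_THRESHOLD_MM) {
  stopifnot(Rs > 0, A >= 0, D > 0, c_surface > 0, c_threshold > 0,
            c_threshold < c_surface)
  structure(list(Rs = Rs, A = A, D = D, c_surface = c_surface,
                 c_threshold = c_threshold),
            class = "sphere_model")
}

#' Radial concentration profile for a constant-rate sphere
#'
#' Closed form for steady diffusion with a uniform sink in a sphere:
#' `c(b) = A/(6 D) * (b^2 - Rs^2) + c_surface`.  The value may be negative
#' near the centre; a negative value signals the necrotic-core regime (the
#' constant-rate model is not valid there) and is returned as-is for the
#' caller to interpret.
#'
#' @param model a [sphere_model].
#' @param b radial position(s), m; must lie in `[0, Rs]`.
#' @return concentration(s), mol/m^3.
#' @export
constant_rate_profile <- function(model, b) {
  stopifnot(inherits(model, "sphere_model"))
  if (any(b < 0) || any(b > model$Rs + 1e-12 * model$Rs)) {
    stop("constant_rate_profile(): b must lie within [0, Rs]")
  }
  model$A / (6 * model$D) * (b^2 - model$Rs^2) + model$c_surface
}

#' Radius of the hypoxic core
#'
#' Inverts the constant-rate sphere profile at the hypoxia threshold:
#' `b = sqrt(Rs^2 - 6 D (c_surface - c_threshold) / A)`.  When the argument
#' is negative the whole sphere sits above the threshold and the result is
#' "no hypoxic core", encoded as `NA` with attribute `has_core = FALSE`.
#'
#' @param model a [sphere_model].
#' @return radius in m, or `NA_real_` when no hypoxic core exists.
#' @export
hypoxic_radius <- function(model) {
  stopifnot(inherits(model, "sphere_model"))
  if (model$A <= 0) return(structure(NA_real_, has_core = FALSE))
  arg <- model$Rs^2 - 6 * model$D * (model$c_surface - model$c_threshold) / model$A
  if (arg < 0) return(structure(NA_real_, has_core = FALSE))
  structure(sqrt(arg), has_core = TRUE)
}

#' One-dimensional Michaelis-Menten radial oracle
#'
#' Independent high-resolution solver for the spherically symmetric
#' diffusion-consumption balance
#' `(1/b^2) d/db (b^2 D dc/db) = Vmax c / (c + Km)` with symmetry at the
#' centre and a Dirichlet surface value.  Solved by Newton iteration on a
#' second-order finite-difference discretization with at least 200 nodes;
#' used as the oracle against which the 3D solver is checked, so it shares
#' no code with the 3D path.
#'
#' @param Rs sphere radius, m.
#' @param D diffusivity, m^2/s.
#' @param Vmax maximum consumption rate, mol/(m^3 s).
#' @param Km Michaelis constant, mol/m^3.
#' @param c_surface surface concentration, mol/m^3.
#' @param tol nonlinear convergence tolerance (relative).
#' @param n number of radial intervals (>= 200 nodes are used regardless).
#' @return list with `b` (radii) and `c` (concentrations), plus the surface
#'   diffusive influx `influx` (mol/s) and total consumption `consumed`
#'   (mol/s) for conservation checking.
#' @export
mm_radial_oracle <- function(Rs, D, Vmax, Km, c_surface,
                             tol = 1e-10, n = 800) {
  stopifnot(Rs > 0, D > 0, Vmax >= 0, Km > 0, c_surface > 0)
  n <- max(n, 200L)
  h <- Rs / n
  b <- seq(0, Rs, length.out = n + 1)
  c <- rep(c_surface, n + 1)

  rate <- function(cc) Vmax * pmax(cc, 0) / (pmax(cc, 0) + Km)

  # Monotone Picard linearization R(c) ~ [Vmax/(c_old+Km)] c: keeps the
  # tridiagonal system an M-matrix and the iterates nonnegative even in the
  # strong-depletion (near-anoxic-core) regime where a plain Newton step
  # oscillates across the clipping set.  Node n+1 is the Dirichlet surface.
  i <- 2:n
  bm <- (b[i] - h / 2)^2
  bp <- (b[i] + h / 2)^2
  lower <- numeric(n); upper <- numeric(n)
  lower[i] <- D * bm / (h^2 * b[i]^2)
  upper[i] <- D * bp / (h^2 * b[i]^2)
  upper[1] <- 6 * D / h^2
  lap_diag <- numeric(n)
  lap_diag[1] <- -6 * D / h^2
  lap_diag[i] <- -(lower[i] + upper[i])
  rhs_bc <- numeric(n)
  rhs_bc[n] <- -upper[n] * c_surface   # surface Dirichlet into the RHS

  delta <- Inf
  for (iter in 1:500) {
    lin <- Vmax / (pmax(c[1:n], 0) + Km)
    diag_ <- lap_diag - lin
    c_new <- thomas_solve(lower, diag_, upper, rhs_bc)
    delta <- max(abs(c_new - c[1:n]))
    c[1:n] <- c_new
    if (delta <= tol * c_surface) break
  }
  if (delta > tol * c_surface) {
    stop("mm_radial_oracle(): Picard iteration failed to converge")
  }

  # conservation diagnostics: influx across the surface vs consumed volume
  dcdb_R <- (3 * c[n + 1] - 4 * c[n] + c[n - 1]) / (2 * h)
  influx <- 4 * pi * Rs^2 * D * dcdb_R
  shell_r <- (b[-1] + b[-(n + 1)]) / 2
  shell_c <- (c[-1] + c[-(n + 1)]) / 2
  consumed <- sum(rate(shell_c) * 4 * pi * shell_r^2 * h)
  list(b = b, c = c, influx = influx, consumed = consumed)
}

# Thomas algorithm for tridiagonal systems; lower[1] and upper[n] unused.
thomas_solve <- function(lower, diag_, upper, rhs) {
  n <- length(diag_)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag_[1]
  dp[1] <- rhs[1] / diag_[1]
  for (i in 2:n) {
    m <- diag_[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Two-layer series-resistance slab
#'
#' Closed-form steady flux through two material layers in series in the
#' partition-scaled variable `phi = c / S`.  With layer conductances
#' `k_i = D_i S_i / L_i`, the interface value is
#' `phi* = (k1 phi0 + k2 phiL) / (k1 + k2)` and the flux `k1 (phi0 - phi*)`.
#'
#' @param k1,k2 layer conductances, m/s (times unit area).
#' @param phi0,phiL partition-scaled boundary values.
#' @return list with `phi_interface` and `flux`.
#' @export
two_layer_slab <- function(k1, k2, phi0, phiL) {
  stopifnot(k1 > 0, k2 > 0)
  phi_star <- (k1 * phi0 + k2 * phiL) / (k1 + k2)
  list(phi_interface = phi_star, flux = k1 * (phi0 - phi_star))
}

#' Manufactured solutions for solver verification
#'
#' Registered smooth exact fields on the unit box (scaled by `L`) together
#' with the forcing that makes them exact solutions of the discretized
#' equations' continuum counterparts.  Used by the order-of-convergence
#' tests.
#'
#' Cases:
#' \describe{
#'   \item{`div_free_velocity`}{`u = U0 (sin(pi y/L), sin(pi z/L), sin(pi x/L))`,
#'     exactly divergence-free, with the Stokes forcing for pressure
#'     `p = mu U0 / L cos(pi x/L) cos(pi y/L) cos(pi z/L)`.}
#'   \item{`diffusion`}{`c = c0 cos(pi x/L) cos(pi y/L) cos(pi z/L)` with the
#'     source balancing `-D lap(c)`.}
#'   \item{`advection_diffusion`}{same `c` advected by a uniform velocity.}
#' }
#'
#' @param name case name.
#' @param L box edge length, m.
#' @param D scalar diffusivity for the transport cases, m^2/s.
#' @param U0 velocity scale, m/s.
#' @param c0 concentration scale, mol/m^3.
#' @param mu viscosity for the Stokes case, Pa s.
#' @param vel uniform advecting velocity (length-3) for `advection_diffusion`.
#' @return a list of exact-field and forcing functions of `(x, y, z)`.
#' @export
manufactured_case <- function(name, L = 1e-3, D = 1e-9, U0 = 1e-4,
                              c0 = 1, mu = 1e-3,
                              vel = c(1e-4, 5e-5, -7e-5)) {
  k <- pi / L
  trip <- function(x, y, z) cos(k * x) * cos(k * y) * cos(k * z)
  switch(name,
    div_free_velocity = {
      p0 <- mu * U0 / L
      list(
        name = name, L = L, mu = mu,
        u = function(x, y, z) U0 * sin(k * y),
        v = function(x, y, z) U0 * sin(k * z),
        w = function(x, y, z) U0 * sin(k * x),
        p = function(x, y, z) p0 * trip(x, y, z),
        # f = -mu lap(u) + grad(p)
        fx = function(x, y, z) mu * U0 * k^2 * sin(k * y) -
          p0 * k * sin(k * x) * cos(k * y) * cos(k * z),
        fy = function(x, y, z) mu * U0 * k^2 * sin(k * z) -
          p0 * k * cos(k * x) * sin(k * y) * cos(k * z),
        fz = function(x, y, z) mu * U0 * k^2 * sin(k * x) -
          p0 * k * cos(k * x) * cos(k * y) * sin(k * z)
      )
    },
    diffusion = {
      list(
        name = name, L = L, D = D,
        c = function(x, y, z) c0 * trip(x, y, z),
        # q = -D lap(c) = 3 D k^2 c
        source = function(x, y, z) 3 * D * k^2 * c0 * trip(x, y, z),
        vel = c(0, 0, 0)
      )
    },
    advection_diffusion = {
      list(
        name = name, L = L, D = D, vel = vel,
        c = function(x, y, z) c0 * trip(x, y, z),
        source = function(x, y, z) {
          adv <- -c0 * k * (vel[1] * sin(k * x) * cos(k * y) * cos(k * z) +
                            vel[2] * cos(k * x) * sin(k * y) * cos(k * z) +
                            vel[3] * cos(k * x) * cos(k * y) * sin(k * z))
          adv + 3 * D * k^2 * c0 * trip(x, y, z)
        }
      )
    },
    stop("manufactured_case(): unknown case '", name, "'")
  )
}
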