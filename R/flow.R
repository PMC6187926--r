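# Steady incompressible flow of the culture medium on the labelled voxel
# grid: staggered (MAC) finite-volume discretization of the Stokes equations
# with stair-step solid masking, solved by conjugate gradients on the
# pressure Schur complement (Uzawa), with ILU(0)-preconditioned CG inner
# solves for the per-component momentum Laplacians.  An optional Picard loop
# adds the inertial term for fidelity to the full momentum balance; at the
# device's Reynolds number (~0.1) its effect is negligible.

#' Solver settings
#'
#' @param flow_residual_tol convergence criterion for the continuity and
#'   momentum residuals (relative), default 1e-6.
#' @param transport_residual_tol convergence criterion for the nonlinear
#'   transport residual (relative), default 1e-3; acceptance runs use a
#'   stricter effective value via `transport_tight`.
#' @param picard_relaxation under-relaxation for Picard loops in (0, 1].
#' @param max_iterations cap on outer (Uzawa / Picard) iterations.
#' @param linear_tol relative tolerance for inner Krylov solves.
#' @param schur_tol relative tolerance for the pressure Schur CG; kept tight
#'   so that the recovered velocity is discretely divergence-free well below
#'   `flow_residual_tol` and global mass balance holds to ~1e-9.
#' @param max_linear_iters cap on inner Krylov iterations.
#' @param include_inertia solve with the convective momentum term via Picard
#'   (default FALSE: Stokes limit, valid for Re << 1).
#' @param advection_scheme transport face scheme: `"powerlaw"` (default;
#'   Patankar power-law, second-order at low cell Peclet, upwind-limited),
#'   `"upwind"` or `"central"`.
#' @param verbose print iteration progress.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(flow_residual_tol = 1e-6,
                            transport_residual_tol = 1e-3,
                            picard_relaxation = 0.7,
                            max_iterations = 200L,
                            linear_tol = 1e-9,
                            schur_tol = 1e-9,
                            max_linear_iters = 50000L,
                            include_inertia = FALSE,
                            advection_scheme = c("powerlaw", "upwind",
                                                 "central"),
                            verbose = FALSE) {
  advection_scheme <- match.arg(advection_scheme)
  stopifnot(flow_residual_tol > 0, transport_residual_tol > 0,
            picard_relaxation > 0, picard_relaxation <= 1,
            max_iterations >= 1)
  structure(list(flow_residual_tol = flow_residual_tol,
                 transport_residual_tol = transport_residual_tol,
                 picard_relaxation = picard_relaxation,
                 max_iterations = as.integer(max_iterations),
                 linear_tol = linear_tol, schur_tol = schur_tol,
                 max_linear_iters = as.integer(max_linear_iters),
                 include_inertia = include_inertia,
                 advection_scheme = advection_scheme,
                 verbose = verbose),
            class = "solver_settings")
}

# shifted lookup: out[idx] = A[idx + dvec], `fill` outside the array.
shift3 <- function(A, dvec, fill = 0L) {
  d <- dim(A)
  out <- array(fill, d)
  dst <- src <- vector("list", 3)
  for (ax in 1:3) {
    s <- dvec[ax]
    if (s >= 0) {
      dst[[ax]] <- seq_len(d[ax] - s); src[[ax]] <- seq_len(d[ax] - s) + s
    } else {
      dst[[ax]] <- seq_len(d[ax] + s) - s; src[[ax]] <- seq_len(d[ax] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}

#' Fully developed inlet velocity profile
#'
#' Solves the constant-pressure-gradient duct problem on the open inlet
#' cross-section (no-slip on its solid perimeter, zero normal gradient on
#' symmetry edges) and rescales the result so that the integrated flux
#' matches the requested flow rate exactly.  When the section has no no-slip
#' perimeter at all (free-slip box), the profile is uniform.
#'
#' @param Q full-device volumetric flow rate, m^3/s.  On half-width grids
#'   the modeled section receives `Q * width_fraction`.
#' @param grid a `labeled_grid`.
#' @return list with `values` (ny x nz matrix of face velocities, zero on
#'   closed cells), `open` (logical matrix) and `flux` (m^3/s, modeled).
#' @export
inlet_profile <- function(Q, grid) {
  stopifnot(Q > 0, inherits(grid, "labeled_grid"))
  d <- grid$dims
  h <- grid$spacing
  open <- grid$label[1, , , drop = TRUE] == REGION_LABELS[["MEDIUM"]]
  dim(open) <- d[2:3]
  if (!any(open)) stop("inlet_profile(): fully blocked inlet")
  idx <- array(0L, d[2:3])
  idx[open] <- seq_len(sum(open))
  n <- sum(open)
  trips_i <- integer(0); trips_j <- integer(0); trips_x <- numeric(0)
  diag_ <- rep(0, n)
  any_wall <- FALSE
  for (dv in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- matrix(0L, d[2], d[3])
    inb <- matrix(FALSE, d[2], d[3])
    r_j <- seq_len(d[2]); r_k <- seq_len(d[3])
    sj <- dv[1]; sk <- dv[2]
    dj <- r_j[r_j + sj >= 1 & r_j + sj <= d[2]]
    dk <- r_k[r_k + sk >= 1 & r_k + sk <= d[3]]
    nb[dj, dk] <- idx[dj + sj, dk + sk]
    inb[dj, dk] <- TRUE
    # in-bounds open neighbour: standard coupling; in-bounds closed: no-slip
    # wall at the half-cell; out of bounds: spanwise (j) edges are symmetry,
    # vertical (k) edges are no-slip walls.
    m_open <- open & inb & nb > 0L
    m_wall <- (open & inb & nb == 0L) | (open & !inb & sk != 0L)
    any_wall <- any_wall || any(m_wall)
    trips_i <- c(trips_i, idx[m_open]); trips_j <- c(trips_j, nb[m_open])
    trips_x <- c(trips_x, rep(-1, sum(m_open)))
    diag_[idx[m_open]] <- diag_[idx[m_open]] + 1
    diag_[idx[m_wall]] <- diag_[idx[m_wall]] + 2
  }
  q_target <- Q * grid$width_fraction
  vals <- matrix(0, d[2], d[3])
  if (!any_wall) {
    vals[open] <- q_target / (n * h^2)
  } else {
    A <- Matrix::sparseMatrix(i = c(trips_i, seq_len(n)),
                              j = c(trips_j, seq_len(n)),
                              x = c(trips_x, diag_) / h^2, dims = c(n, n))
    u <- as.numeric(Matrix::solve(A, rep(1, n)))
    u <- u * q_target / (sum(u) * h^2)
    vals[open] <- u
  }
  list(values = vals, open = open, flux = q_target)
}

# permutations putting each component's own axis first
.comp_perm <- list(u = c(1L, 2L, 3L), v = c(2L, 1L, 3L), w = c(3L, 1L, 2L))
# physical axis (1=x,2=y,3=z) corresponding to each canonical axis
.comp_phys <- list(u = c(1L, 2L, 3L), v = c(2L, 1L, 3L), w = c(3L, 1L, 2L))

# Assemble one momentum component in its canonical frame.
# Returns A (dgCMatrix), rhs, G (dgCMatrix nu x np), uidx (canonical array),
# kv_known (canonical array of imposed face values), ftype.
assemble_momentum_component <- function(comp, grid, mu, pidx, prof, mms) {
  h <- grid$spacing
  perm <- .comp_perm[[comp]]
  phys <- .comp_phys[[comp]]
  fl <- grid$label == REGION_LABELS[["MEDIUM"]]
  fl_c <- aperm(fl, perm)
  dc <- dim(fl_c)
  fd <- dc + c(1L, 0L, 0L)
  n1 <- dc[1]

  # face type and imposed values ---------------------------------------------
  ftype <- array(1L, fd)                      # 1 = known (default value 0)
  kv <- array(0, fd)
  uk <- array(FALSE, fd)
  uk[2:n1, , ] <- fl_c[1:(n1 - 1), , ] & fl_c[2:n1, , ]
  ftype[uk] <- 0L

  axc <- grid_axes(grid)
  face_coords <- function() {
    # canonical face-centre coordinates as three fd-arrays (physical x,y,z)
    o <- grid$origin[phys]
    a1 <- o[1] + (seq_len(fd[1]) - 1) * h
    a2 <- o[2] + (seq_len(fd[2]) - 0.5) * h
    a3 <- o[3] + (seq_len(fd[3]) - 0.5) * h
    cc <- list(array(rep(a1, times = fd[2] * fd[3]), fd),
               array(rep(rep(a2, each = fd[1]), times = fd[3]), fd),
               array(rep(a3, each = fd[1] * fd[2]), fd))
    out <- vector("list", 3)
    out[phys] <- cc                            # out[[1]]=x, out[[2]]=y, out[[3]]=z
    out
  }

  if (!is.null(mms)) {
    xyz <- face_coords()
    exact <- mms[[comp]]
    vals <- exact(xyz[[1]], xyz[[2]], xyz[[3]])
    # normal-boundary faces carry the exact value
    kv[1, , ] <- vals[1, , ]
    kv[fd[1], , ] <- vals[fd[1], , ]
  } else if (comp == "u") {
    kv[1, , ] <- prof$values                   # inlet profile
    out_open <- fl_c[n1, , , drop = FALSE]
    ftype[fd[1], , ][out_open[1, , ]] <- 2L    # outlet: zero-gradient
  }

  uidx <- array(0L, fd)
  nu <- sum(uk)
  uidx[uk] <- seq_len(nu)

  # adjacency to non-fluid cells, face-aligned
  nfL <- array(TRUE, fd); nfL[2:fd[1], , ] <- !fl_c
  nfR <- array(TRUE, fd); nfR[1:n1, , ] <- !fl_c

  w <- mu / h^2
  diag_ <- rep(0, nu)
  rhs <- rep(0, nu)
  ti <- vector("list", 12); tj <- vector("list", 12); tx <- vector("list", 12)
  nt <- 0L

  add_coupling <- function(mask, nb) {
    nt <<- nt + 1L
    ti[[nt]] <<- uidx[mask]; tj[[nt]] <<- nb[mask]
    tx[[nt]] <<- rep(-w, sum(mask))
  }

  # tangential boundary treatment per canonical axis/side:
  #   "sym": zero normal gradient; "wall": no-slip at the half cell
  tang_bc <- function(ax_can, side) {
    pax <- phys[ax_can]
    if (!is.null(mms)) return("wall")          # Dirichlet everywhere (g from mms)
    if (pax == 2L) return("sym")               # spanwise symmetry
    if (pax == 3L) return("wall")              # floor / lid: no-slip
    if (side == "lo") return("wall")           # inlet plane: profile is normal only
    "sym"                                      # outlet: zero gradient
  }
  tang_g <- function(ax_can, side) {
    if (is.null(mms)) return(NULL)             # g = 0
    xyz <- face_coords()
    pax <- phys[ax_can]
    bound <- if (side == "lo") grid$origin[pax] else {
      grid$origin[pax] + dim(fl)[pax] * h
    }
    xyz[[pax]] <- array(bound, fd)
    mms[[comp]](xyz[[1]], xyz[[2]], xyz[[3]])
  }

  for (dirspec in list(list(ax = 1L, s = 1L), list(ax = 1L, s = -1L),
                       list(ax = 2L, s = 1L), list(ax = 2L, s = -1L),
                       list(ax = 3L, s = 1L), list(ax = 3L, s = -1L))) {
    dvec <- c(0L, 0L, 0L); dvec[dirspec$ax] <- dirspec$s
    nbU <- shift3(uidx, dvec, 0L)
    if (dirspec$ax == 1L) {
      nbT <- shift3(ftype, dvec, 1L)
      nbK <- shift3(kv, dvec, 0)
      mA <- uk & nbU > 0L
      mB <- uk & nbU == 0L & nbT == 1L
      mN <- uk & nbU == 0L & nbT == 2L
      add_coupling(mA, nbU)
      diag_[uidx[mA]] <- diag_[uidx[mA]] + w
      diag_[uidx[mB]] <- diag_[uidx[mB]] + w
      rhs[uidx[mB]] <- rhs[uidx[mB]] + w * nbK[mB]
      # mN: zero-gradient -> no contribution
    } else {
      inb_arr <- shift3(array(TRUE, fd), dvec, FALSE)
      wall_nb <- shift3(nfL, dvec, TRUE) & shift3(nfR, dvec, TRUE)
      nbK <- shift3(kv, dvec, 0)
      mA <- uk & inb_arr & nbU > 0L
      mWall <- uk & inb_arr & nbU == 0L & wall_nb
      mB <- uk & inb_arr & nbU == 0L & !wall_nb
      mOOB <- uk & !inb_arr
      add_coupling(mA, nbU)
      diag_[uidx[mA]] <- diag_[uidx[mA]] + w
      diag_[uidx[mB]] <- diag_[uidx[mB]] + w
      rhs[uidx[mB]] <- rhs[uidx[mB]] + w * nbK[mB]
      diag_[uidx[mWall]] <- diag_[uidx[mWall]] + 2 * w
      if (any(mOOB)) {
        side <- if (dirspec$s < 0L) "lo" else "hi"
        bc <- tang_bc(dirspec$ax, side)
        if (bc == "wall") {
          diag_[uidx[mOOB]] <- diag_[uidx[mOOB]] + 2 * w
          g <- tang_g(dirspec$ax, side)
          if (!is.null(g)) rhs[uidx[mOOB]] <- rhs[uidx[mOOB]] + 2 * w * g[mOOB]
        }
        # "sym": no contribution
      }
    }
  }

  A <- Matrix::sparseMatrix(i = c(unlist(ti[seq_len(nt)]), seq_len(nu)),
                            j = c(unlist(tj[seq_len(nt)]), seq_len(nu)),
                            x = c(unlist(tx[seq_len(nt)]), diag_),
                            dims = c(nu, nu))

  # body force (manufactured cases)
  if (!is.null(mms) && !is.null(mms[[paste0("f", comp)]])) {
    xyz <- face_coords()
    fv <- mms[[paste0("f", comp)]](xyz[[1]], xyz[[2]], xyz[[3]])
    rhs <- rhs + fv[uk]
  }

  # pressure gradient operator -----------------------------------------------
  pidx_c <- aperm(pidx, perm)
  pL <- array(0L, fd); pL[2:fd[1], , ] <- pidx_c
  pR <- array(0L, fd); pR[1:n1, , ] <- pidx_c
  np <- max(pidx)
  mR <- uk & pR > 0L
  mL <- uk & pL > 0L
  G <- Matrix::sparseMatrix(i = c(uidx[mR], uidx[mL]),
                            j = c(pR[mR], pL[mL]),
                            x = c(rep(1 / h, sum(mR)), rep(-1 / h, sum(mL))),
                            dims = c(nu, np))

  kv_known <- kv
  kv_known[ftype != 1L] <- 0
  list(A = A, rhs = rhs, G = G, uidx = uidx, uk = uk, kv_known = kv_known,
       ftype = ftype, perm = perm, nu = nu)
}

#' Solve steady incompressible flow
#'
#' Imposes the fully developed inlet profile, a zero-pressure outflow at the
#' downstream end, free-slip on symmetry sides and no-slip on every surface
#' in contact with the medium (channel walls, trap, aggregate; the velocity
#' inside the aggregate is identically zero).  Solves the Stokes limit by
#' default; `include_inertia = TRUE` adds the convective term through
#' deferred-correction Picard iterations.
#'
#' @param grid a `labeled_grid`.
#' @param params a [physical_params].
#' @param settings a [solver_settings].
#' @param mms internal hook for manufactured-solution verification: a list
#'   of exact field functions `u,v,w` (and optional forcings `fu,fv,fw`)
#'   of `(x,y,z)`; all domain boundaries then become Dirichlet.
#' @return an object of class `flow_field` with staggered face-velocity
#'   arrays `u`, `v`, `w`, cell pressures `p`, and `diagnostics`.
#' @export
solve_flow <- function(grid, params = default_physical_params(),
                       settings = solver_settings(), mms = NULL) {
  stopifnot(inherits(grid, "labeled_grid"))
  d <- grid$dims
  h <- grid$spacing
  mu <- params$mu
  fl <- grid$label == REGION_LABELS[["MEDIUM"]]
  if (!any(fl)) stop("solve_flow(): no medium cells in grid")

  prof <- NULL
  if (is.null(mms)) {
    if (!any(fl[1, , ])) stop("solve_flow(): grid has no INLET faces")
    if (!any(fl[d[1], , ])) stop("solve_flow(): grid has no OUTLET faces")
    prof <- inlet_profile(params$Q, grid)
  }

  # pressure unknowns: fluid cells with at least one unknown face, excluding
  # the outlet reference layer (p = 0 there) or a single pinned cell (mms).
  uk_u <- array(FALSE, d + c(1L, 0L, 0L))
  uk_u[2:d[1], , ] <- fl[1:(d[1] - 1), , ] & fl[2:d[1], , ]
  uk_v <- array(FALSE, d + c(0L, 1L, 0L))
  uk_v[, 2:d[2], ] <- fl[, 1:(d[2] - 1), ] & fl[, 2:d[2], ]
  uk_w <- array(FALSE, d + c(0L, 0L, 1L))
  uk_w[, , 2:d[3]] <- fl[, , 1:(d[3] - 1)] & fl[, , 2:d[3]]
  has_face <- (uk_u[1:d[1], , ] | uk_u[2:(d[1] + 1L), , ] |
               uk_v[, 1:d[2], ] | uk_v[, 2:(d[2] + 1L), ] |
               uk_w[, , 1:d[3]] | uk_w[, , 2:(d[3] + 1L)])
  pmask <- fl & has_face
  if (is.null(mms)) {
    ref <- array(FALSE, d); ref[d[1], , ] <- TRUE
    pmask <- pmask & !ref
  } else {
    first_fluid <- which(pmask)[1]
    pmask[first_fluid] <- FALSE
  }
  np <- sum(pmask)
  pidx <- array(0L, d)
  pidx[pmask] <- seq_len(np)

  comps <- c("u", "v", "w")
  asm <- lapply(comps, assemble_momentum_component, grid = grid, mu = mu,
                pidx = pidx, prof = prof, mms = mms)
  names(asm) <- comps
  solvers <- lapply(asm, function(a) sparse_solver(a$A, milu = TRUE))

  # continuity right-hand side from imposed faces
  KU <- aperm(asm$u$kv_known, order(asm$u$perm))
  KV <- aperm(asm$v$kv_known, order(asm$v$perm))
  KW <- aperm(asm$w$kv_known, order(asm$w$perm))
  div_known <- (KU[2:(d[1] + 1L), , ] - KU[1:d[1], , ] +
                KV[, 2:(d[2] + 1L), ] - KV[, 1:d[2], ] +
                KW[, , 2:(d[3] + 1L)] - KW[, , 1:d[3]]) / h
  gvec <- div_known[pmask]

  lt <- settings$linear_tol
  mli <- settings$max_linear_iters
  solveA <- function(comp, b, x0 = NULL) {
    krylov_solve(solvers[[comp]], b, x0 = x0, tol = lt, maxit = mli,
                 method = "cg", context = paste0("momentum ", comp))$x
  }

  picard_iters <- if (settings$include_inertia) settings$max_iterations else 1L
  f_extra <- lapply(asm, function(a) rep(0, a$nu))
  field <- NULL
  resid_hist <- c()

  for (picard in seq_len(picard_iters)) {
    u0 <- lapply(comps, function(cc) solveA(cc, asm[[cc]]$rhs + f_extra[[cc]]))
    names(u0) <- comps
    rhs_s <- -gvec
    for (cc in comps) rhs_s <- rhs_s + as.numeric(Matrix::crossprod(asm[[cc]]$G, u0[[cc]]))

    applyS <- function(p) {
      out <- numeric(np)
      for (cc in comps) {
        gp <- as.numeric(asm[[cc]]$G %*% p)
        q <- solveA(cc, gp)
        out <- out + as.numeric(Matrix::crossprod(asm[[cc]]$G, q))
      }
      out
    }
    p_sol <- schur_cg(applyS, rhs_s, tol = settings$schur_tol,
                      maxit = settings$max_iterations * 10L,
                      verbose = settings$verbose)
    resid_hist <- c(resid_hist, p_sol$relres)

    usol <- lapply(comps, function(cc) {
      solveA(cc, asm[[cc]]$rhs + f_extra[[cc]] -
                   as.numeric(asm[[cc]]$G %*% p_sol$x), x0 = u0[[cc]])
    })
    names(usol) <- comps

    U <- array(0, d + c(1L, 0L, 0L)); V <- array(0, d + c(0L, 1L, 0L))
    W <- array(0, d + c(0L, 0L, 1L))
    fill_comp <- function(a, sol) {
      arr <- a$kv_known
      arr[a$uk] <- sol
      aperm(arr, order(a$perm))
    }
    U <- fill_comp(asm$u, usol$u)
    V <- fill_comp(asm$v, usol$v)
    W <- fill_comp(asm$w, usol$w)

    if (is.null(mms)) {
      # outlet faces: zero-gradient carry-out corrected to close the local
      # mass balance of the (unenforced) reference layer exactly
      i <- d[1]
      out_open <- fl[i, , ]
      dv <- V[i, 2:(d[2] + 1L), ] - V[i, 1:d[2], ]
      dw <- W[i, , 2:(d[3] + 1L)] - W[i, , 1:d[3]]
      U[i + 1L, , ][out_open] <- (U[i, , ] - dv - dw)[out_open]
    }

    new_field <- list(u = U, v = V, w = W)
    if (settings$include_inertia) {
      fadv <- inertia_forcing(grid, new_field, params$rho, asm)
      delta <- max(vapply(comps, function(cc)
        max(abs(fadv[[cc]] - f_extra[[cc]])), numeric(1)))
      scale <- max(vapply(comps, function(cc)
        max(abs(fadv[[cc]]), 1e-300), numeric(1)))
      w_rel <- settings$picard_relaxation
      for (cc in comps) {
        f_extra[[cc]] <- (1 - w_rel) * f_extra[[cc]] - w_rel * fadv[[cc]]
      }
      field <- new_field
      if (delta <= 1e-3 * scale || picard == picard_iters) break
    } else {
      field <- new_field
      break
    }
  }

  p_arr <- array(0, d)
  p_arr[pmask] <- p_sol$x

  # diagnostics ---------------------------------------------------------------
  divv <- (field$u[2:(d[1] + 1L), , ] - field$u[1:d[1], , ] +
           field$v[, 2:(d[2] + 1L), ] - field$v[, 1:d[2], ] +
           field$w[, , 2:(d[3] + 1L)] - field$w[, , 1:d[3]]) / h
  max_div <- max(abs(divv[fl]))
  u_scale <- max(abs(field$u), abs(field$v), abs(field$w), 1e-300)
  q_in <- if (is.null(mms)) sum(field$u[1, , ] * h^2) else NA_real_
  q_out <- if (is.null(mms)) sum(field$u[d[1] + 1L, , ] * h^2) else NA_real_

  structure(list(
    u = field$u, v = field$v, w = field$w, p = p_arr, grid = grid,
    settings = settings,
    diagnostics = list(
      schur_relres = p_sol$relres, schur_iters = p_sol$iters,
      residual_history = resid_hist,
      max_divergence = max_div, velocity_scale = u_scale,
      mass_tol = max_div * h / u_scale,
      Q_in = q_in, Q_out = q_out,
      mass_balance = if (is.null(mms)) abs(q_out - q_in) / abs(q_in) else NA_real_,
      inlet_profile = prof)),
    class = "flow_field")
}

# CG on the (SPD) pressure Schur complement.
schur_cg <- function(applyS, rhs, tol, maxit, verbose = FALSE) {
  n <- length(rhs)
  x <- numeric(n)
  r <- rhs
  bn <- sqrt(sum(rhs^2))
  if (bn == 0) return(list(x = x, relres = 0, iters = 0L))
  p <- r
  rz <- sum(r * r)
  relres <- 1
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Sp <- applyS(p)
    pAp <- sum(p * Sp)
    if (pAp <= 0) break
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Sp
    rz_new <- sum(r * r)
    relres <- sqrt(rz_new) / bn
    hist <- c(hist, relres)
    if (verbose) message(sprintf("  schur cg %d: relres %.3e", it, relres))
    if (relres <= tol) {
      return(list(x = x, relres = relres, iters = it, history = hist))
    }
    beta <- rz_new / rz
    rz <- rz_new
    p <- r + beta * p
  }
  stop(sprintf(paste0("solve_flow(): pressure iteration failed to reach ",
                      "tolerance %.1e (relres %.3e after %d iterations; ",
                      "history tail: %s)"),
               tol, relres, maxit,
               paste(signif(utils::tail(hist, 5), 3), collapse = ", ")))
}

# index an array along one axis
index_along <- function(A, ax, idx) {
  args <- rep(list(quote(expr = )), 3)
  args[[ax]] <- idx
  do.call(`[`, c(list(A), args, list(drop = FALSE)))
}

# central gradient with one-sided differences at array edges
clamped_grad <- function(A, ax, h) {
  n <- dim(A)[ax]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  num <- index_along(A, ax, ip) - index_along(A, ax, im)
  den <- (ip - im) * h
  sweep_dims <- dim(A)
  scale <- array(rep(den, each = prod(sweep_dims[seq_len(ax - 1)])),
                 sweep_dims)
  num / scale
}

# average a staggered component B (staggered along axis `bax`) onto the faces
# of component `cax` (face array dims fd): 4-point mean with edge clamping
stagger_avg <- function(B, bax, cax, fd) {
  # first average along bax onto cell centres
  nb <- dim(B)[bax]
  Bc <- (index_along(B, bax, seq_len(nb - 1L)) +
         index_along(B, bax, seq_len(nb)[-1])) / 2
  # then average along cax onto the cax faces, clamping at the boundary
  nc <- dim(Bc)[cax]
  iL <- pmax(seq_len(nc + 1L) - 1L, 1L)
  iR <- pmin(seq_len(nc + 1L), nc)
  out <- (index_along(Bc, cax, iL) + index_along(Bc, cax, iR)) / 2
  stopifnot(all(dim(out) == fd))
  out
}

# Deferred-correction convective forcing rho (V . grad) V sampled at the
# unknown faces of each component (Picard fidelity loop; Re << 1 use).
inertia_forcing <- function(grid, field, rho, asm) {
  h <- grid$spacing
  ax_of <- c(u = 1L, v = 2L, w = 3L)
  out <- list()
  for (comp in c("u", "v", "w")) {
    arr <- field[[comp]]
    cax <- ax_of[[comp]]
    adv <- arr * clamped_grad(arr, cax, h)
    for (oc in setdiff(c("u", "v", "w"), comp)) {
      bax <- ax_of[[oc]]
      adv <- adv + stagger_avg(field[[oc]], bax, cax, dim(arr)) *
        clamped_grad(arr, bax, h)
    }
    a <- asm[[comp]]
    adv_c <- aperm(adv, a$perm)
    out[[comp]] <- rho * adv_c[a$uk]
  }
  out
}

#' @export
print.flow_field <- function(x, ...) {
  d <- x$grid$dims
  dg <- x$diagnostics
  cat(sprintf("flow_field on %d x %d x %d grid\n", d[1], d[2], d[3]))
  cat(sprintf("  max |div| = %.3e 1/s, mass balance = %.3e\n",
              dg$max_divergence, dg$mass_balance))
  invisible(x)
}

#' Flow diagnostics report
#'
#' Scalar diagnostics of a converged flow field: Reynolds number based on
#' the mean inlet velocity and channel height, cell Peclet bounds for the
#' default species, mass balance and residuals.
#'
#' @param field a `flow_field`.
#' @return named list of diagnostics.
#' @export
flow_report <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  grid <- field$grid
  h <- grid$spacing
  dg <- field$diagnostics
  u_max <- max(abs(field$u), abs(field$v), abs(field$w))
  spec <- grid$spec
  re <- NA_real_
  if (!is.null(spec)) {
    params <- default_physical_params()
    U_mean <- params$Q / (spec$channel_width * spec$channel_height)
    re <- params$rho * U_mean * spec$channel_height / params$mu
  }
  peclet <- vapply(c(oxygen = "oxygen", glucose = "glucose"), function(s) {
    u_max * h / default_species(s)$D_medium
  }, numeric(1))
  list(Re = re, max_velocity = u_max, cell_peclet = peclet,
       mass_balance = dg$mass_balance, max_divergence = dg$max_divergence,
       Q_in = dg$Q_in, Q_out = dg$Q_out,
       schur_relres = dg$schur_relres, schur_iters = dg$schur_iters)
}
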