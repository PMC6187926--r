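# Steady conjugate species transport on the labelled grid.
#
# The solver works in the partition-scaled variable phi = c / S_region
# (S_medium = 1).  Writing the diffusive flux as D S grad(phi) makes phi
# continuous across material interfaces while reproducing both interface
# conditions exactly: flux continuity and the solubility concentration jump
# c_region = S_region * c_medium.  This turns the jump problem into an
# ordinary heterogeneous-coefficient diffusion problem with face coefficient
# beta = D * S, discretized with harmonic means.  This is the single most
# important discretization decision in the transport module.
#
# Advection acts only on medium-medium faces (velocity is zero elsewhere);
# face fluxes use Patankar's power-law scheme by default (upwind and central
# available).  The Michaelis-Menten sink is linearized per Picard iteration
# as Vmax/(c_old + Km) * c_new, which keeps the system an M-matrix and the
# iterate nonnegative.

#' Michaelis-Menten consumption rate
#'
#' `R = Vmax * c / (c + Km)`: monotone in `c`, bounded by `Vmax`, half the
#' maximum at `c = Km`.
#'
#' @param c concentration(s), mol/m^3; must be nonnegative.
#' @param Vmax maximum rate, mol/(m^3 s).
#' @param Km Michaelis constant, mol/m^3.
#' @return consumption rate(s), mol/(m^3 s).
#' @export
mm_rate <- function(c, Vmax, Km) {
  stopifnot(Vmax >= 0, Km > 0)
  if (any(c < 0)) stop("mm_rate(): negative concentration")
  Vmax * c / (c + Km)
}

# Solubility ratio and beta = D * S per cell for a species.
species_region_props <- function(grid, species) {
  lbl <- grid$label
  S <- array(NA_real_, dim(lbl))
  beta <- array(NA_real_, dim(lbl))
  M <- REGION_LABELS
  S[lbl == M[["MEDIUM"]]] <- 1
  beta[lbl == M[["MEDIUM"]]] <- species$D_medium
  S[lbl == M[["TISSUE"]]] <- species$S_tissue
  beta[lbl == M[["TISSUE"]]] <- species$D_tissue * species$S_tissue
  if (species$pdms_permeable) {
    S[lbl == M[["PDMS"]]] <- species$S_pdms
    beta[lbl == M[["PDMS"]]] <- species$D_pdms * species$S_pdms
  }
  list(S = S, beta = beta, admissible = !is.na(S))
}

#' Assemble the discrete transport operator
#'
#' Builds the conservative finite-volume system for one species in the
#' partition-scaled variable phi = c/S on the union of its admissible
#' regions (oxygen: medium, PDMS, tissue; glucose: medium, tissue).
#' Boundary data: inlet phi = c_inlet; outlet advective carry-out with zero
#' diffusive flux; symmetry and other walls no-flux; for a PDMS-permeable
#' species the lid top is held at phi = c_inlet (i.e. c = S_pdms * c_inlet,
#' the ambient-equilibrium condition).  If the grid carries a
#' `dirichlet_exterior` value, faces towards EXTERIOR cells impose that
#' concentration at the true (signed-distance) interface position.
#'
#' The Michaelis-Menten sink is *not* included here; [solve_species()] adds
#' its Picard linearization per iteration.
#'
#' @param grid a `labeled_grid`.
#' @param species a [species_spec].
#' @param flow a `flow_field`, or `NULL` for a quiescent medium (allowed
#'   only with `assume_still = TRUE` when medium cells exist).
#' @param settings a [solver_settings] (chooses the advection scheme).
#' @param assume_still treat a missing flow field as zero velocity.
#' @param mms manufactured-solution hook: list with functions `c(x,y,z)`
#'   (Dirichlet data applied on every exterior face) and `source(x,y,z)`.
#' @return list with the base operator `A` (dgCMatrix, no reaction), right
#'   hand side `b`, index array `cidx`, admissibility mask, per-cell `S`,
#'   tissue linear indices, and boundary-face bookkeeping for flux audits.
#' @export
assemble_transport <- function(grid, species, flow = NULL,
                               settings = solver_settings(),
                               assume_still = FALSE, mms = NULL) {
  stopifnot(inherits(grid, "labeled_grid"), inherits(species, "species_spec"))
  d <- grid$dims
  h <- grid$spacing
  props <- species_region_props(grid, species)
  adm <- props$admissible
  if (!any(adm)) stop("assemble_transport(): no admissible cells for species")
  M <- REGION_LABELS
  has_medium <- any(grid$label == M[["MEDIUM"]])
  if (is.null(flow) && has_medium && !assume_still && is.null(mms)) {
    stop("assemble_transport(): flow field required while MEDIUM cells exist ",
         "(pass assume_still = TRUE for a quiescent medium)")
  }

  n <- sum(adm)
  cidx <- array(0L, d)
  cidx[adm] <- seq_len(n)
  scheme <- settings$advection_scheme
  Afun <- switch(scheme,
    powerlaw = function(P) pmax(0, (1 - 0.1 * abs(P))^5),
    upwind = function(P) rep(1, length(P)),
    central = function(P) pmax(0, 1 - 0.5 * abs(P)))

  diag_ <- rep(0, n)
  b <- rep(0, n)
  ti <- list(); tj <- list(); tx <- list(); nt <- 0L
  bnd <- list()  # boundary-face audit records

  face_flux <- function(ax) {
    # volumetric flux arrays on interior faces along axis ax, from flow
    if (is.null(flow)) return(NULL)
    switch(ax,
           flow$u * h^2,
           flow$v * h^2,
           flow$w * h^2)
  }

  slice_lo <- function(A, ax) {
    switch(ax, A[1:(d[1] - 1), , , drop = FALSE],
               A[, 1:(d[2] - 1), , drop = FALSE],
               A[, , 1:(d[3] - 1), drop = FALSE])
  }
  slice_hi <- function(A, ax) {
    switch(ax, A[2:d[1], , , drop = FALSE],
               A[, 2:d[2], , drop = FALSE],
               A[, , 2:d[3], drop = FALSE])
  }

  for (ax in 1:3) {
    admL <- slice_lo(adm, ax); admR <- slice_hi(adm, ax)
    pair <- admL & admR
    if (!any(pair)) next
    iL <- slice_lo(cidx, ax)[pair]; iR <- slice_hi(cidx, ax)[pair]
    bL <- slice_lo(props$beta, ax)[pair]; bR <- slice_hi(props$beta, ax)[pair]
    Dc <- 2 * bL * bR / (bL + bR) * h          # conductance, m^3/s units/(mol/m^3)
    Fa <- 0
    if (!is.null(flow)) {
      fx <- face_flux(ax)
      inner <- switch(ax, fx[2:d[1], , , drop = FALSE],
                          fx[, 2:d[2], , drop = FALSE],
                          fx[, , 2:d[3], drop = FALSE])
      Fa <- inner[pair]                        # signed L -> R
    }
    Pe <- ifelse(Dc > 0, Fa / Dc, 0)
    DA <- Dc * Afun(Pe)
    aR <- DA + pmax(-Fa, 0)   # neighbour coefficient seen from L
    aL <- DA + pmax(Fa, 0)    # neighbour coefficient seen from R
    nt <- nt + 1L; ti[[nt]] <- iL; tj[[nt]] <- iR; tx[[nt]] <- -aR
    nt <- nt + 1L; ti[[nt]] <- iR; tj[[nt]] <- iL; tx[[nt]] <- -aL
    diag_base <- DA
    dl <- diag_base + pmax(Fa, 0)   # = aR + Fa
    dr <- diag_base + pmax(-Fa, 0)  # = aL - Fa
    diag_[iL] <- diag_[iL] + dl
    diag_[iR] <- diag_[iR] + dr
  }

  add_dirichlet <- function(cells, Dc_b, F_out, phi_b, what) {
    # F_out: signed outward volumetric flux through the face
    Pe <- ifelse(Dc_b > 0, F_out / Dc_b, 0)
    DA <- Dc_b * Afun(Pe)
    aN <- DA + pmax(-F_out, 0)
    diag_[cells] <<- diag_[cells] + aN + F_out
    b[cells] <<- b[cells] + aN * phi_b
    bnd[[length(bnd) + 1L]] <<- list(cells = cells, aN = aN, F_out = F_out,
                                     phi_b = phi_b, what = what)
  }

  co <- NULL
  if (!is.null(mms)) {
    co <- grid_coord_arrays(grid)
    # every exterior face of an admissible cell is Dirichlet with mms data
    for (ax in 1:3) {
      for (side in c("lo", "hi")) {
        pick <- function(A) {
          if (side == "lo") {
            switch(ax, A[1, , , drop = FALSE], A[, 1, , drop = FALSE],
                   A[, , 1, drop = FALSE])
          } else {
            switch(ax, A[d[1], , , drop = FALSE], A[, d[2], , drop = FALSE],
                   A[, , d[3], drop = FALSE])
          }
        }
        msk <- pick(adm)
        cells <- pick(cidx)[msk]
        xb <- pick(co$x)[msk]; yb <- pick(co$y)[msk]; zb <- pick(co$z)[msk]
        off <- h / 2 * (if (side == "lo") -1 else 1)
        if (ax == 1) xb <- xb + off
        if (ax == 2) yb <- yb + off
        if (ax == 3) zb <- zb + off
        phi_b <- mms$c(xb, yb, zb)
        bnl <- pick(props$beta)[msk]
        F_out <- 0
        if (!is.null(flow)) {
          farr <- face_flux(ax)
          bf <- if (side == "lo") {
            switch(ax, farr[1, , , drop = FALSE], farr[, 1, , drop = FALSE],
                   farr[, , 1, drop = FALSE])
          } else {
            switch(ax, farr[d[1] + 1, , , drop = FALSE],
                   farr[, d[2] + 1, , drop = FALSE],
                   farr[, , d[3] + 1, drop = FALSE])
          }
          F_out <- bf[msk] * (if (side == "lo") -1 else 1)
        }
        add_dirichlet(cells, 2 * bnl * h, F_out, phi_b,
                      paste0("mms_", ax, side))
      }
    }
    b <- b + mms$source(co$x, co$y, co$z)[adm] * h^3
  } else {
    # inlet: medium cells on the x-lo plane
    inlet_cells <- grid$label[1, , ] == M[["MEDIUM"]]
    if (any(inlet_cells) && !is.null(flow)) {
      cells <- cidx[1, , ][inlet_cells]
      F_in <- (flow$u[1, , ] * h^2)[inlet_cells]
      add_dirichlet(cells, 2 * species$D_medium * h, -F_in,
                    species$c_inlet, "inlet")
    } else if (any(inlet_cells)) {
      cells <- cidx[1, , ][inlet_cells]
      add_dirichlet(cells, 2 * species$D_medium * h, 0,
                    species$c_inlet, "inlet")
    }
    # outlet: advective carry-out only
    outlet_cells <- grid$label[d[1], , ] == M[["MEDIUM"]]
    if (any(outlet_cells) && !is.null(flow)) {
      cells <- cidx[d[1], , ][outlet_cells]
      F_out <- (flow$u[d[1] + 1, , ] * h^2)[outlet_cells]
      add_dirichlet(cells, 0, F_out, 0, "outlet")
    }
    # ambient lid top for PDMS-permeable species
    if (species$pdms_permeable && !is.null(grid$spec) &&
        grid$spec$lid_thickness > 0) {
      lid_cells <- grid$label[, , d[3]] == M[["PDMS"]]
      if (any(lid_cells)) {
        cells <- cidx[, , d[3]][lid_cells]
        bpd <- species$D_pdms * species$S_pdms
        add_dirichlet(cells, rep(2 * bpd * h, length(cells)), 0,
                      species$c_inlet, "lid_ambient")
      }
    }
    # Dirichlet towards EXTERIOR cells (validation fixtures).  The stored
    # value is the concentration on the adjacent cell's side of the surface
    # (scalar, or a function of the face position); the interface position
    # comes from the signed distance when available (sub-cell accuracy),
    # otherwise the face plane is used.
    if (!is.null(grid$dirichlet_exterior)) {
      ext <- grid$label == M[["EXTERIOR"]]
      co_d <- grid_coord_arrays(grid)
      for (ax in 1:3) {
        for (sgn in c(-1L, 1L)) {
          dvec <- c(0L, 0L, 0L); dvec[ax] <- sgn
          nb_ext <- shift3(ext, dvec, FALSE)   # domain walls stay no-flux
          msk <- adm & nb_ext
          if (!any(msk)) next
          if (!is.null(grid$sdf)) {
            sdf_in <- grid$sdf[msk]
            sdf_out <- shift3(grid$sdf, dvec, NA_real_)[msk]
            theta <- ifelse(is.na(sdf_out) | (abs(sdf_in) + abs(sdf_out)) == 0,
                            0.5, abs(sdf_in) / (abs(sdf_in) + abs(sdf_out)))
            theta <- pmin(pmax(theta, 0.05), 1)
          } else theta <- 0.5
          cells <- cidx[msk]
          bcell <- props$beta[msk]
          val <- if (is.function(grid$dirichlet_exterior)) {
            xb <- co_d$x[msk]; yb <- co_d$y[msk]; zb <- co_d$z[msk]
            if (ax == 1) xb <- xb + sgn * h / 2
            if (ax == 2) yb <- yb + sgn * h / 2
            if (ax == 3) zb <- zb + sgn * h / 2
            grid$dirichlet_exterior(xb, yb, zb)
          } else grid$dirichlet_exterior
          phi_surf <- val / props$S[msk]
          add_dirichlet(cells, bcell * h / theta, 0, phi_surf,
                        "exterior_surface")
        }
      }
    }
  }

  A <- Matrix::sparseMatrix(i = c(unlist(ti), seq_len(n)),
                            j = c(unlist(tj), seq_len(n)),
                            x = c(unlist(tx), diag_), dims = c(n, n))
  tissue_cells <- cidx[grid$label == M[["TISSUE"]] & adm]
  list(A = A, b = b, cidx = cidx, admissible = adm, S = props$S,
       beta = props$beta, tissue = tissue_cells, species = species,
       boundary = bnd, has_advection = !is.null(flow),
       grid = grid, n = n)
}

#' Solve steady species transport
#'
#' Picard iteration on the Michaelis-Menten sink (rate linearized about the
#' previous iterate, reaction argument clipped at zero) until the relative
#' l2 residual of the nonlinear system falls below
#' `settings$transport_residual_tol`.  Returns concentrations `c = S * phi`
#' on the species' admissible regions.
#'
#' @inheritParams assemble_transport
#' @param constant_rate if not `NULL`, replace the Michaelis-Menten sink by
#'   a uniform zeroth-order rate (mol/(m^3 s)) in the tissue; the problem is
#'   then linear and solved in one pass (used by the analytical validation).
#' @return an object of class `concentration_field` with array `c`
#'   (`NA` outside the admissible regions), `phi`, iteration diagnostics and
#'   a boundary-flux audit.
#' @export
solve_species <- function(grid, species, flow = NULL,
                          settings = solver_settings(),
                          assume_still = FALSE, mms = NULL,
                          constant_rate = NULL) {
  sys <- assemble_transport(grid, species, flow, settings, assume_still, mms)
  n <- sys$n
  h <- grid$spacing
  vol <- h^3
  S_adm <- sys$S[sys$admissible]
  phi <- rep(species$c_inlet, n)
  tis <- sys$tissue
  tol <- settings$transport_residual_tol
  relax <- settings$picard_relaxation
  method <- if (sys$has_advection) "bicgstab" else "cg"
  # Residuals are normalized by the residual of the trivial uniform-inlet
  # state (CFD "first-iteration" scaling): |b| itself is dominated by large
  # Dirichlet conductance terms and would make the criterion far too loose.
  r0 <- as.numeric(sys$A %*% phi) - sys$b
  if (length(tis) && species$Vmax > 0 && is.null(mms)) {
    c0v <- pmax(S_adm[tis] * phi[tis], 0)
    r0[tis] <- r0[tis] + vol * species$Vmax * c0v / (c0v + species$Km)
  }
  bscale <- sqrt(sum(r0^2))
  if (bscale == 0) bscale <- sqrt(sum(sys$b^2))
  if (bscale == 0) bscale <- 1
  residual <- NA_real_
  res_hist <- numeric(0)
  iters <- 0L

  if (!is.null(constant_rate)) {
    b2 <- sys$b
    b2[tis] <- b2[tis] - constant_rate * vol
    sol <- krylov_solve(sparse_solver(sys$A), b2, x0 = phi,
                        tol = settings$linear_tol,
                        maxit = settings$max_linear_iters,
                        method = method, context = "transport (constant rate)")
    phi <- sol$x
    residual <- sol$relres
    iters <- 1L
  } else if (length(tis) == 0 || species$Vmax == 0 || !is.null(mms)) {
    sol <- krylov_solve(sparse_solver(sys$A), sys$b, x0 = phi,
                        tol = settings$linear_tol,
                        maxit = settings$max_linear_iters,
                        method = method, context = "transport (linear)")
    phi <- sol$x
    residual <- sol$relres
    iters <- 1L
  } else {
    Stis <- S_adm[tis]
    # inner solves must land the linear residual well below the nonlinear
    # target (which is scaled by the initial residual, not by |b|)
    bnorm <- max(sqrt(sum(sys$b^2)), 1e-300)
    lin_tol <- max(min(settings$linear_tol, 0.05 * tol * bscale / bnorm),
                   1e-13)
    for (k in seq_len(settings$max_iterations)) {
      c_old <- pmax(Stis * phi[tis], 0)
      react_diag <- vol * species$Vmax * Stis / (c_old + species$Km)
      Ak <- sys$A + Matrix::sparseMatrix(i = tis, j = tis, x = react_diag,
                                         dims = c(n, n))
      sol <- krylov_solve(sparse_solver(Ak), sys$b, x0 = phi,
                          tol = lin_tol,
                          maxit = settings$max_linear_iters,
                          method = method, context = "transport Picard")
      phi_new <- phi + relax * (sol$x - phi)
      # nonlinear residual: operator re-evaluated at the new iterate
      c_new <- pmax(Stis * phi_new[tis], 0)
      resid_vec <- as.numeric(sys$A %*% phi_new) - sys$b
      resid_vec[tis] <- resid_vec[tis] +
        vol * species$Vmax * c_new / (c_new + species$Km)
      residual <- sqrt(sum(resid_vec^2)) / bscale
      res_hist <- c(res_hist, residual)
      phi <- phi_new
      iters <- k
      if (residual <= tol) break
    }
    if (residual > tol) {
      stop(sprintf(paste0("solve_species(): Picard failed to converge ",
                          "(residual %.3e > %.1e; history tail: %s)"),
                   residual, tol,
                   paste(signif(utils::tail(res_hist, 5), 3), collapse = ", ")))
    }
  }

  neg_floor <- -1e3 * .Machine$double.eps * max(abs(phi), species$c_inlet)
  if (min(phi) < neg_floor && is.null(mms) && is.null(constant_rate)) {
    stop(sprintf("solve_species(): converged solution has negative cells (min phi = %.3e)",
                 min(phi)))
  }

  carr <- array(NA_real_, grid$dims)
  parr <- array(NA_real_, grid$dims)
  parr[sys$admissible] <- phi
  carr[sys$admissible] <- phi * S_adm

  # boundary-flux audit: net influx through Dirichlet/outflow faces and total
  # consumption, which must balance at steady state.
  influx <- 0
  for (rec in sys$boundary) {
    # inward flux through the face: aN (phi_b - phi_P) - F_out phi_P
    influx <- influx +
      sum(rec$aN * (rec$phi_b - phi[rec$cells]) - rec$F_out * phi[rec$cells])
  }
  consumed <- if (length(tis) && is.null(mms)) {
    if (!is.null(constant_rate)) {
      constant_rate * vol * length(tis)
    } else {
      cc <- pmax(S_adm[tis] * phi[tis], 0)
      sum(vol * species$Vmax * cc / (cc + species$Km))
    }
  } else 0

  structure(list(c = carr, phi = parr, species = species, grid = grid,
                 iterations = iters, residual = residual,
                 residual_history = res_hist,
                 influx = influx, consumed = consumed,
                 system = sys),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  rng <- range(x$c, na.rm = TRUE)
  cat(sprintf("concentration_field '%s': c in [%.4g, %.4g] mM, %d iterations (residual %.2e)\n",
              x$species$name, rng[1], rng[2], x$iterations, x$residual))
  invisible(x)
}
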