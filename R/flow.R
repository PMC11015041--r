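#' Solve the steady interstitial fluid pressure problem
#'
#' Cell-centered finite-volume discretization of Darcy flow with Starling
#' transvascular exchange,
#' `-div(K grad p) = phi_B - phi_L`, where
#' `phi_B = Lp (S/V) [p_B - p - sigma_s (pi_B - pi_i)]` is the capillary
#' source and `phi_L = LpL (SL/V) [p - p_L]` the lymphatic sink (normal
#' tissue only; tumor tissue has no functional lymphatics). The hydraulic
#' conductivity `K` is piecewise constant by tissue with harmonic averaging
#' at faces, which makes pressure and normal flux continuous across the
#' tumor-normal interface by construction. The interstitial pressure is
#' fixed to zero on the outer boundary of the labeled domain, and the
#' velocity is `v = -K grad p`.
#'
#' The linear system is symmetric positive definite (all Starling terms are
#' linear in `p`) and is solved by diagonally preconditioned conjugate
#' gradients.
#'
#' @param phantom A [make_spherical_phantom()]-style `psma_phantom`.
#' @param params A [load_parameters()] `psma_params` object.
#' @param tol Relative residual tolerance of the linear solve.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @param forcing Optional array (phantom dimensions) of an extra volumetric
#'   source, 1/s — used by manufactured-solution verification cases.
#' @return A `psma_flow` object: `p_i` pressure array (Pa; `NA` outside the
#'   domain), face-velocity arrays `vx`, `vy`, `vz` (cm/s, on the staggered
#'   face grids), Starling fields `phi_B` and `phi_L` (1/s),
#'   `residual_norm`, `iterations`, and a `fluid_balance` list comparing the
#'   net Starling production with the boundary outflow.
#' @export
solve_ifp <- function(phantom, params, tol = 1e-10, max_iter = 20000L,
                      forcing = NULL) {
  stopifnot(inherits(phantom, "psma_phantom"), inherits(params, "psma_params"))
  lab <- phantom$labels
  d <- dim(lab)
  h <- phantom$spacing
  ft <- tissue_flow_table(params)
  # per-voxel coefficient arrays (0 outside)
  tiss <- array(0L, d); tiss[lab == 1L] <- 1L; tiss[lab == 2L] <- 2L
  pick <- function(col) {
    v <- array(0, d)
    v[tiss == 1L] <- ft[[col]][ft$tissue == "normal"]
    v[tiss == 2L] <- ft[[col]][ft$tissue == "tumor"]
    v
  }
  Kv   <- pick("K")
  sB   <- pick("Lp") * pick("S_V")
  sL   <- pick("LpL_SL_V")
  p_e  <- pick("p_e")
  p_L  <- pick("p_L")

  inside <- tiss > 0L
  n_eq <- sum(inside)
  if (n_eq == 0) rlang::abort("Phantom has no tissue voxels.")
  eq <- array(NA_integer_, d)
  eq[inside] <- seq_len(n_eq)
  if (!.single_connected_component(array(as.integer(inside), d), 1L)) {
    rlang::abort("Tissue region is disconnected.", class = "psmatrans_flow_error")
  }

  diag_acc <- sB[inside] + sL[inside]
  rhs <- sB[inside] * p_e[inside] + sL[inside] * p_L[inside]
  if (!is.null(forcing)) {
    stopifnot(all(dim(forcing) == d))
    rhs <- rhs + forcing[inside]
  }

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (axis in 1:3) {
    # interior faces: pairs (low cell, high cell) both inside
    nl <- d[axis]
    idx_lo <- slice.index(lab, axis) < nl
    shift <- function(a) {
      # neighbor value in +axis direction
      if (axis == 1) a[c(2:d[1], 1), , , drop = FALSE]
      else if (axis == 2) a[, c(2:d[2], 1), , drop = FALSE]
      else a[, , c(2:d[3], 1), drop = FALSE]
    }
    in_hi <- shift(inside); K_hi <- shift(Kv); eq_hi <- shift(eq)
    pair <- idx_lo & inside & in_hi
    if (any(pair)) {
      Kh <- 2 * Kv[pair] * K_hi[pair] / (Kv[pair] + K_hi[pair])
      Tf <- Kh / h[axis]^2
      a <- eq[pair]; b <- eq_hi[pair]
      ii <- c(ii, a, b, a, b); jj <- c(jj, a, b, b, a)
      xx <- c(xx, Tf, Tf, -Tf, -Tf)
    }
    # Dirichlet faces: inside cell whose +axis or -axis neighbor is outside
    # the labeled box or label 0 (half-cell distance to the p = 0 face)
    bd_hi <- idx_lo & inside & !in_hi
    bd_hi_edge <- (slice.index(lab, axis) == nl) & inside
    in_lo <- shift(inside)  # reuse: compute -axis neighbor via reverse shift
    shift_dn <- function(a) {
      if (axis == 1) a[c(1, 1:(d[1] - 1)), , , drop = FALSE]
      else if (axis == 2) a[, c(1, 1:(d[2] - 1)), , drop = FALSE]
      else a[, , c(1, 1:(d[3] - 1)), drop = FALSE]
    }
    in_dn <- shift_dn(inside)
    bd_lo <- (slice.index(lab, axis) > 1) & inside & !in_dn
    bd_lo_edge <- (slice.index(lab, axis) == 1) & inside
    for (bd in list(bd_hi, bd_hi_edge, bd_lo, bd_lo_edge)) {
      if (any(bd)) {
        a <- eq[bd]
        ii <- c(ii, a); jj <- c(jj, a)
        xx <- c(xx, 2 * Kv[bd] / h[axis]^2)
      }
    }
  }
  diag_idx <- seq_len(n_eq)
  A <- Matrix::sparseMatrix(i = c(ii, diag_idx), j = c(jj, diag_idx),
                            x = c(xx, diag_acc), dims = c(n_eq, n_eq))

  sol <- .cg_solve(A, rhs, x0 = p_e[inside], tol = tol, max_iter = max_iter)
  p <- array(NA_real_, d)
  p[inside] <- sol$x

  # Starling fields on the solution
  phi_B <- array(0, d); phi_L <- array(0, d)
  phi_B[inside] <- sB[inside] * (p_e[inside] - sol$x)
  phi_L[inside] <- sL[inside] * (sol$x - p_L[inside])

  vel <- .face_velocities(p, Kv, inside, h)

  # discrete global balance: net Starling production vs boundary outflow
  vox <- prod(h)
  production <- sum((phi_B[inside] - phi_L[inside])) * vox
  if (!is.null(forcing)) production <- production + sum(forcing[inside]) * vox
  outflow <- .boundary_outflow(vel, inside, h)

  structure(list(p_i = p, vx = vel$vx, vy = vel$vy, vz = vel$vz,
                 phi_B = phi_B, phi_L = phi_L,
                 residual_norm = sol$rel_res, iterations = sol$iter,
                 fluid_balance = list(production = production, outflow = outflow,
                                      rel_error = abs(production - outflow) /
                                        max(abs(production), .Machine$double.eps)),
                 phantom = phantom),
            class = "psma_flow")
}

# Jacobi-preconditioned conjugate gradients for the SPD flow system
.cg_solve <- function(A, b, x0, tol, max_iter) {
  Dinv <- 1 / Matrix::diag(A)
  x <- x0
  r <- b - as.numeric(A %*% x)
  z <- Dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) bnorm <- 1
  iter <- 0L
  repeat {
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol || iter >= max_iter) break
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    iter <- iter + 1L
  }
  if (sqrt(sum(r^2)) / bnorm > tol) {
    rlang::abort(paste0("Pressure solve did not converge in ", max_iter,
                        " iterations (relative residual ",
                        signif(sqrt(sum(r^2)) / bnorm, 3), ")."),
                 class = "psmatrans_flow_error")
  }
  list(x = x, rel_res = sqrt(sum(r^2)) / bnorm, iter = iter)
}

# staggered face velocities v = -K dp/dn; outside-domain faces use the
# Dirichlet p = 0 half-cell gradient
.face_velocities <- function(p, Kv, inside, h) {
  d <- dim(p)
  mk <- function(axis) {
    dd <- d; dd[axis] <- d[axis] + 1
    v <- array(0, dd)
    v
  }
  vx <- mk(1); vy <- mk(2); vz <- mk(3)
  p0 <- ifelse(inside, p, 0)
  for (axis in 1:3) {
    v <- list(vx, vy, vz)[[axis]]
    nl <- d[axis]
    # interior faces f = 2..nl between cells f-1 and f
    idx_all <- function(i) switch(axis,
                                  list(i, TRUE, TRUE), list(TRUE, i, TRUE), list(TRUE, TRUE, i))
    for (f in 2:nl) {
      aL <- do.call(`[`, c(list(p0), idx_all(f - 1), list(drop = FALSE)))
      aR <- do.call(`[`, c(list(p0), idx_all(f), list(drop = FALSE)))
      inL <- do.call(`[`, c(list(inside), idx_all(f - 1), list(drop = FALSE)))
      inR <- do.call(`[`, c(list(inside), idx_all(f), list(drop = FALSE)))
      KL <- do.call(`[`, c(list(Kv), idx_all(f - 1), list(drop = FALSE)))
      KR <- do.call(`[`, c(list(Kv), idx_all(f), list(drop = FALSE)))
      Kh <- ifelse(inL & inR, 2 * KL * KR / pmax(KL + KR, .Machine$double.xmin),
                   ifelse(inL, 2 * KL, ifelse(inR, 2 * KR, 0)))
      grad <- ifelse(inL & inR, (aR - aL) / h[axis],
                     ifelse(inL, (0 - aL) / h[axis],     # half-cell, K doubled above
                            ifelse(inR, (aR - 0) / h[axis], 0)))
      vf <- -Kh * grad
      v <- do.call(`[<-`, c(list(v), idx_all(f), list(vf)))
    }
    # outermost faces (1 and nl+1): Dirichlet if the adjacent cell is inside
    aR <- do.call(`[`, c(list(p0), idx_all(1), list(drop = FALSE)))
    inR <- do.call(`[`, c(list(inside), idx_all(1), list(drop = FALSE)))
    KR <- do.call(`[`, c(list(Kv), idx_all(1), list(drop = FALSE)))
    v <- do.call(`[<-`, c(list(v), idx_all(1),
                          list(ifelse(inR, -2 * KR * (aR - 0) / h[axis], 0))))
    aL <- do.call(`[`, c(list(p0), idx_all(nl), list(drop = FALSE)))
    inL <- do.call(`[`, c(list(inside), idx_all(nl), list(drop = FALSE)))
    KL <- do.call(`[`, c(list(Kv), idx_all(nl), list(drop = FALSE)))
    v <- do.call(`[<-`, c(list(v), idx_all(nl + 1),
                          list(ifelse(inL, -2 * KL * (0 - aL) / h[axis], 0))))
    if (axis == 1) vx <- v else if (axis == 2) vy <- v else vz <- v
  }
  list(vx = vx, vy = vy, vz = vz)
}

# net volumetric outflow through all domain-boundary faces, cm^3/s ... here
# per cm^3 units cancel to cm^3/s given face area * velocity
.boundary_outflow <- function(vel, inside, h) {
  d <- dim(inside)
  area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])
  out <- 0
  for (axis in 1:3) {
    v <- list(vel$vx, vel$vy, vel$vz)[[axis]]
    nl <- d[axis]
    idx_all <- function(i) switch(axis,
                                  list(i, TRUE, TRUE), list(TRUE, i, TRUE), list(TRUE, TRUE, i))
    get <- function(a, i) do.call(`[`, c(list(a), idx_all(i), list(drop = FALSE)))
    for (f in seq_len(nl + 1)) {
      inL <- if (f >= 2) get(inside, f - 1) else array(FALSE, dim(get(inside, 1)))
      inR <- if (f <= nl) get(inside, f) else array(FALSE, dim(get(inside, 1)))
      bd <- xor(inL, inR)
      if (!any(bd)) next
      vf <- get(v, f)
      sgn <- ifelse(inL & !inR, 1, -1)  # outward is +axis if the inside cell is on the low side
      out <- out + sum((vf * sgn * area[axis])[bd])
    }
  }
  out
}

#' Evaluate Starling source/sink fields for a given pressure
#'
#' Pointwise evaluation of the capillary source
#' `phi_B = Lp (S/V) [p_B - p_i - sigma_s (pi_B - pi_i)]` and lymphatic sink
#' `phi_L = LpL (SL/V) [p_i - p_L]` (clamped to normal tissue) with
#' per-tissue parameters.
#'
#' @param p_i Pressure array (Pa) on the phantom grid.
#' @param params A `psma_params`.
#' @param phantom The `psma_phantom` supplying tissue labels.
#' @return List with arrays `phi_B` and `phi_L` (1/s; zero outside tissue).
#' @export
starling_fields <- function(p_i, params, phantom) {
  lab <- phantom$labels
  stopifnot(all(dim(p_i) == dim(lab)))
  ft <- tissue_flow_table(params)
  phi_B <- array(0, dim(lab)); phi_L <- array(0, dim(lab))
  for (tt in c("normal", "tumor")) {
    row <- ft[ft$tissue == tt, ]
    m <- lab == (if (tt == "normal") 1L else 2L)
    phi_B[m] <- row$Lp * row$S_V * (row$p_e - p_i[m])
    phi_L[m] <- row$LpL_SL_V * (p_i[m] - row$p_L)
  }
  list(phi_B = phi_B, phi_L = phi_L)
}

#' @export
print.psma_flow <- function(x, ...) {
  tum <- x$phantom$labels == 2L
  nor <- x$phantom$labels == 1L
  cat("<psma_flow> solved in", x$iterations, "CG iterations, rel. residual",
      signif(x$residual_norm, 3), "\n")
  cat("  tumor IFP: mean", signif(mean(x$p_i[tum]), 5), "Pa; normal mean",
      signif(mean(x$p_i[nor]), 5), "Pa\n")
  cat("  fluid balance rel. error:", signif(x$fluid_balance$rel_error, 3), "\n")
  invisible(x)
}

#' Tidy one-row summary of a flow solution
#'
#' @param x A `psma_flow`.
#' @param ... Unused.
#' @return One-row tibble: central tumor IFP, mean tumor/normal IFP, maximum
#'   face-velocity magnitude, fluid-balance relative error and solver
#'   diagnostics.
#' @method glance psma_flow
#' @export
glance.psma_flow <- function(x, ...) {
  lab <- x$phantom$labels
  d <- dim(lab)
  ctr <- ceiling(d / 2)
  vmax <- max(abs(x$vx), abs(x$vy), abs(x$vz))
  tibble(
    p_center = x$p_i[ctr[1], ctr[2], ctr[3]],
    p_tumor_mean = mean(x$p_i[lab == 2L]),
    p_normal_mean = mean(x$p_i[lab == 1L]),
    v_max = vmax,
    fluid_balance_rel_error = x$fluid_balance$rel_error,
    cg_iterations = x$iterations,
    residual_norm = x$residual_norm
  )
}

#' Radial profile of pressure and velocity magnitude
#'
#' Emulates cut-line diagnostics: samples voxels by distance from the domain
#' center and averages within radial bins.
#'
#' @param flow A `psma_flow`.
#' @param n_bins Number of radial bins.
#' @return Tibble with `r` (cm), mean `p_i` (Pa), mean `|v|` (cm/s,
#'   cell-centered average of face values) and the dominant tissue label.
#' @export
radial_profile <- function(flow, n_bins = 30) {
  ph <- flow$phantom
  d <- dim(ph$labels)
  ax <- .axis_coords(ph)
  ctr <- vapply(ax, function(a) mean(range(a)), numeric(1))
  r <- sqrt(outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                  (ax[[3]] - ctr[3])^2, `+`))
  vmag <- .cell_speed(flow)
  inside <- ph$labels > 0L
  bins <- cut(r[inside], breaks = n_bins)
  tibble(r = tapply(r[inside], bins, mean),
         p_i = tapply(flow$p_i[inside], bins, mean),
         v_mag = tapply(vmag[inside], bins, mean),
         label = tapply(ph$labels[inside], bins, function(l) round(mean(l)))) |>
    filter(!is.na(.data$r))
}

# cell-centered speed from staggered face velocities
.cell_speed <- function(flow) {
  d <- dim(flow$p_i)
  cx <- (flow$vx[1:d[1], , , drop = FALSE] + flow$vx[2:(d[1] + 1), , , drop = FALSE]) / 2
  cy <- (flow$vy[, 1:d[2], , drop = FALSE] + flow$vy[, 2:(d[2] + 1), , drop = FALSE]) / 2
  cz <- (flow$vz[, , 1:d[3], drop = FALSE] + flow$vz[, , 2:(d[3] + 1), drop = FALSE]) / 2
  sqrt(cx^2 + cy^2 + cz^2)
}

#' Plot the mid-plane interstitial pressure of a flow solution
#'
#' @param object A `psma_flow`.
#' @param ... Unused.
#' @return A ggplot of the central z-slice of IFP with the tumor contour.
#' @method autoplot psma_flow
#' @export
autoplot.psma_flow <- function(object, ...) {
  ph <- object$phantom
  d <- dim(ph$labels)
  k <- ceiling(d[3] / 2)
  ax <- .axis_coords(ph)
  df <- expand.grid(x = ax[[1]], y = ax[[2]])
  df$p <- as.vector(object$p_i[, , k])
  df$tumor <- as.vector(ph$labels[, , k] == 2L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$p)) +
    ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$tumor)),
                          breaks = 0.5, colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "IFP [Pa]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [cm]", y = "y [cm]",
                  title = "Interstitial fluid pressure, mid-plane")
}
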