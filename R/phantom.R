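#' Voxel phantom constructors and I/O
#'
#' A phantom is a 3-D labeled voxel grid standing in for an image-derived
#' tumor geometry: label 0 = outside the computational domain, 1 = normal
#' tissue, 2 = tumor. Voxel centers sit at `origin + index * spacing`
#' (0-based indices); the outer faces of the labeled box form the outer
#' boundary of the computational domain.
#'
#' @name phantom
NULL

.new_phantom <- function(labels, spacing, origin, provenance) {
  stopifnot(length(dim(labels)) == 3, length(spacing) == 3, all(spacing > 0))
  storage.mode(labels) <- "integer"
  vox_vol <- prod(spacing)
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         tumor_volume = sum(labels == 2L) * vox_vol,
         provenance = provenance),
    class = "psma_phantom")
}

#' @export
print.psma_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("<psma_phantom> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " cm\n", sep = "")
  cat("  tumor: ", sum(x$labels == 2L), " voxels (", signif(x$tumor_volume, 4),
      " cm^3); normal: ", sum(x$labels == 1L), "; outside: ",
      sum(x$labels == 0L), "\n", sep = "")
  cat(" ", x$provenance, "\n")
  invisible(x)
}

# physical coordinates of voxel centers along each axis
.axis_coords <- function(phantom) {
  d <- dim(phantom$labels)
  lapply(1:3, function(a) phantom$origin[a] + (seq_len(d[a]) - 1) * phantom$spacing[a])
}

#' Generate a spherical tumor phantom
#'
#' A tumor sphere of radius `tumor_radius` centered in a cube of normal
#' tissue with half-width `domain_half_width`. Deterministic.
#'
#' @param tumor_radius Tumor radius, cm.
#' @param domain_half_width Half-width of the normal-tissue cube, cm; must
#'   exceed `tumor_radius`.
#' @param spacing Isotropic voxel edge, cm. Must satisfy
#'   `spacing <= tumor_radius / 5` so the tumor is resolved.
#' @return A `psma_phantom`.
#' @examples
#' ph <- make_spherical_phantom(0.5, 1.0, 0.1)
#' ph$tumor_volume  # close to 4/3 * pi * 0.5^3
#' @export
make_spherical_phantom <- function(tumor_radius, domain_half_width, spacing) {
  stopifnot(tumor_radius > 0)
  if (tumor_radius >= domain_half_width) {
    rlang::abort("tumor_radius must be strictly smaller than domain_half_width.",
                 class = "psmatrans_phantom_error")
  }
  if (spacing > tumor_radius / 5) {
    rlang::abort(paste0("spacing = ", spacing, " cm is too coarse for a ",
                        tumor_radius, " cm tumor; use spacing <= tumor_radius/5 (",
                        tumor_radius / 5, " cm)."),
                 class = "psmatrans_phantom_error")
  }
  n <- max(3L, as.integer(round(2 * domain_half_width / spacing)))
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  labels <- array(1L, dim = c(n, n, n))
  labels[r2 <= tumor_radius^2] <- 2L
  .new_phantom(labels, rep(spacing, 3), rep(x[1], 3),
               sprintf("sphere r=%g cm in %g cm half-width cube, h=%g cm",
                       tumor_radius, domain_half_width, spacing))
}

#' Generate a lobed ellipsoidal tumor phantom
#'
#' An ellipsoid with a smooth random radial perturbation emulating irregular,
#' lobed tumor shapes. `lobedness = 0` gives the exact ellipsoid. The
#' perturbation field is a fixed-seed combination of low-order directional
#' harmonics, so the phantom is reproducible for a given seed. If a draw
#' disconnects the tumor it is rejected and redrawn (bounded retries).
#'
#' @param semi_axes Numeric triple of ellipsoid semi-axes, cm.
#' @param domain_half_width Half-width of the surrounding normal-tissue cube, cm.
#' @param spacing Isotropic voxel edge, cm (resolution guard on the smallest
#'   semi-axis).
#' @param seed Integer seed for the perturbation.
#' @param lobedness Nonnegative amplitude of the relative radial perturbation.
#' @return A `psma_phantom` with a single connected tumor component.
#' @export
make_ellipsoidal_phantom <- function(semi_axes, domain_half_width, spacing,
                                     seed = 1L, lobedness = 0) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), lobedness >= 0)
  if (max(semi_axes) >= domain_half_width) {
    rlang::abort("semi-axes must be strictly smaller than domain_half_width.",
                 class = "psmatrans_phantom_error")
  }
  if (spacing > min(semi_axes) / 5) {
    rlang::abort("spacing too coarse; use spacing <= min(semi_axes)/5.",
                 class = "psmatrans_phantom_error")
  }
  n <- max(3L, as.integer(round(2 * domain_half_width / spacing)))
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = x, y = x, z = x)
  rho2 <- (g$x / semi_axes[1])^2 + (g$y / semi_axes[2])^2 + (g$z / semi_axes[3])^2
  rng <- .with_local_seed(seed, function() {
    lapply(1:5, function(i) list(u = .unit_vector(), w = stats::rnorm(1)))
  })
  for (attempt in seq_len(8L)) {
    modes <- rng
    if (attempt > 1) {
      modes <- .with_local_seed(seed + attempt * 1000L, function() {
        lapply(1:5, function(i) list(u = .unit_vector(), w = stats::rnorm(1)))
      })
    }
    if (lobedness > 0) {
      r <- sqrt(g$x^2 + g$y^2 + g$z^2)
      r[r == 0] <- 1
      pert <- 0
      for (m in modes) {
        cosang <- (g$x * m$u[1] + g$y * m$u[2] + g$z * m$u[3]) / r
        pert <- pert + m$w * (2 * cosang^2 - 1)
      }
      pert <- pert / sqrt(length(modes))
      boundary <- (1 + lobedness * pert)^2
      boundary <- pmax(boundary, 0.04)  # keep the surface away from the center
    } else {
      boundary <- 1
    }
    labels <- array(1L, dim = c(n, n, n))
    labels[rho2 <= boundary] <- 2L
    if (.single_connected_component(labels, 2L)) {
      ph <- .new_phantom(labels, rep(spacing, 3), rep(x[1], 3),
                         sprintf("lobed ellipsoid a=%s cm, lobedness=%g, seed=%d",
                                 paste(semi_axes, collapse = "/"), lobedness, seed))
      return(ph)
    }
  }
  rlang::abort("Could not generate a connected tumor after 8 attempts; reduce lobedness.",
               class = "psmatrans_phantom_error")
}

.unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# run fn() under a temporary RNG state, restoring the caller's state
.with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# breadth-first flood fill: TRUE if all voxels with the given label form one
# 6-connected component (and at least one such voxel exists)
.single_connected_component <- function(labels, label) {
  idx <- which(labels == label)
  if (length(idx) == 0) return(FALSE)
  d <- dim(labels)
  mask <- labels == label
  visited <- array(FALSE, d)
  strides <- c(1L, d[1], d[1] * d[2])
  ai <- arrayInd(idx[1], d)
  visited[idx[1]] <- TRUE
  frontier <- idx[1]
  nvis <- 1L
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (axis in 1:3) {
      for (sgn in c(-1L, 1L)) {
        pos <- arrayInd(frontier, d)
        pos[, axis] <- pos[, axis] + sgn
        keep <- pos[, axis] >= 1L & pos[, axis] <= d[axis]
        if (!any(keep)) next
        lin <- (pos[keep, 1] - 1L) + (pos[keep, 2] - 1L) * strides[2] +
          (pos[keep, 3] - 1L) * strides[3] + 1L
        lin <- lin[mask[lin] & !visited[lin]]
        if (length(lin) > 0) {
          visited[lin] <- TRUE
          nxt <- c(nxt, lin)
        }
      }
    }
    frontier <- unique(nxt)
    nvis <- nvis + length(frontier)
  }
  sum(visited) == length(idx)
}

#' Read / write phantoms as NIfTI label masks
#'
#' Masks are stored as integer NIfTI volumes with labels in \{0, 1, 2\} and
#' voxel spacing in mm (the format's convention); the in-memory phantom uses
#' cm. Write-then-read round trips preserve labels and spacing exactly.
#'
#' @param phantom A `psma_phantom`.
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `read_mask` returns a `psma_phantom`; `write_mask` returns `path`
#'   invisibly.
#' @export
write_mask <- function(phantom, path) {
  stopifnot(inherits(phantom, "psma_phantom"))
  sp_mm <- phantom$spacing * 10  # cm -> mm
  img <- RNifti::asNifti(phantom$labels, datatype = "int16")
  img <- RNifti::updateNifti(img, template = list(pixdim = c(3, sp_mm, 1, 1, 1, 1)))
  aff <- diag(c(sp_mm, 1))
  aff[1:3, 4] <- phantom$origin * 10
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) {
    rlang::abort("Mask must be a 3-D volume.", class = "psmatrans_format_error")
  }
  if (any(arr != round(arr))) {
    rlang::abort("Mask contains non-integer labels.", class = "psmatrans_format_error")
  }
  bad <- setdiff(unique(as.integer(arr)), c(0L, 1L, 2L))
  if (length(bad) > 0) {
    rlang::abort(paste0("Mask contains labels outside {0,1,2}: ",
                        paste(bad, collapse = ", ")),
                 class = "psmatrans_format_error")
  }
  sp_mm <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp_mm)) || any(sp_mm <= 0)) {
    rlang::abort("Mask is missing positive voxel spacing metadata.",
                 class = "psmatrans_format_error")
  }
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin_mm <- if (!is.null(xf)) xf[1:3, 4] else rep(0, 3)
  labels <- array(as.integer(arr), dim = dim(arr))
  .new_phantom(labels, sp_mm / 10, origin_mm / 10,
               paste0("read from ", basename(path)))
}
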