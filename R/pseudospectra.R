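#' Complex-plane bounding box around a spectrum
#'
#' Axis-aligned box covering all eigenvalues, expanded by `margin` times the
#' larger spectral extent and made symmetric about the real axis (the
#' pseudospectrum of a real matrix is conjugate-symmetric). For a spectrum
#' with no extent (a single point), the fallback half-width is
#' `max(|lambda|, 1) * margin`.
#'
#' @param eigenvalues complex vector (>= 1 value).
#' @param margin expansion fraction, default 0.2.
#' @return list with `re` and `im` two-element ranges.
#' @export
grid_bounds <- function(eigenvalues, margin = 0.2) {
  stopifnot(length(eigenvalues) >= 1)
  re <- range(Re(eigenvalues))
  im_max <- max(abs(Im(eigenvalues)))
  extent <- max(diff(re), 2 * im_max)
  pad <- if (extent > 0) margin * extent else max(max(Mod(eigenvalues)), 1) * margin
  list(re = c(re[1] - pad, re[2] + pad),
       im = c(-(im_max + pad), im_max + pad))
}

#' Minimum-singular-value grid over the complex plane
#'
#' For each grid point `z` computes `sigma_min(zI - A)`, the smallest
#' singular value of the shifted resolvent: the epsilon-pseudospectrum of `A`
#' is the sublevel set where this value is at most epsilon, i.e. the set of
#' eigenvalues of all perturbations of `A` of Frobenius size up to epsilon.
#' Low values away from the spectrum betray eigenvalues that move under small
#' perturbation -- transient behaviour the eigenvalues themselves miss. For
#' real `A` only the closed upper half-plane is computed and mirrored.
#'
#' @param A square matrix.
#' @param box bounds as from [grid_bounds()]; computed from the spectrum of
#'   `A` when omitted.
#' @param resolution grid points per axis (>= 2), default 201.
#' @param levels contour levels (ascending epsilon values) stored with the
#'   grid, default powers of 10 from 1e-8 up to the grid maximum.
#' @return object of class `pseudospectrum_grid`: list with `re`, `im`
#'   coordinate vectors, `sigma_min` matrix (rows index `re`, columns `im`),
#'   `levels`, `eigenvalues`, and metadata.
#' @export
sigma_min_grid <- function(A, box = NULL, resolution = 201L, levels = NULL) {
  stopifnot(resolution >= 2)
  M <- unclass(A)
  ev <- eigen(M, only.values = TRUE)$values
  if (is.null(box)) box <- grid_bounds(ev)
  re <- seq(box$re[1], box$re[2], length.out = resolution)
  im <- seq(box$im[1], box$im[2], length.out = resolution)
  is_real <- all(Im(M) == 0)
  sig <- matrix(NA_real_, resolution, resolution)
  I <- diag(nrow(M))
  smin <- function(z) min(svd(z * I - M, nu = 0, nv = 0)$d)
  if (is_real) {
    upper <- which(im >= 0)
    for (j in upper) for (i in seq_len(resolution))
      sig[i, j] <- smin(complex(real = re[i], imaginary = im[j]))
    for (j in which(im < 0)) {
      # conjugate symmetry: sigma_min at conj(z) equals sigma_min at z
      jj <- which.min(abs(im + im[j]))
      sig[, j] <- if (abs(im[jj] + im[j]) < 1e-12) sig[, jj] else
        vapply(seq_len(resolution), function(i)
          smin(complex(real = re[i], imaginary = im[j])), numeric(1))
    }
  } else {
    for (j in seq_len(resolution)) for (i in seq_len(resolution))
      sig[i, j] <- smin(complex(real = re[i], imaginary = im[j]))
  }
  if (is.null(levels)) {
    top <- max(sig)
    levels <- 10^seq(-8, ceiling(log10(max(top, 1e-7))))
    levels <- levels[levels <= top]
  }
  structure(list(re = re, im = im, sigma_min = sig, levels = levels,
                 eigenvalues = ev,
                 country = attr(A, "country"), year = attr(A, "year"),
                 resolution = as.integer(resolution), bounds = box),
            class = "pseudospectrum_grid")
}

#' @export
print.pseudospectrum_grid <- function(x, ...) {
  cat(sprintf("pseudospectrum grid %dx%d, re [%.3g, %.3g], im [%.3g, %.3g]\n",
              length(x$re), length(x$im), x$re[1], x$re[length(x$re)],
              x$im[1], x$im[length(x$im)]))
  cat(sprintf("  sigma_min range [%.3g, %.3g]; %d contour levels\n",
              min(x$sigma_min), max(x$sigma_min), length(x$levels)))
  invisible(x)
}

# 4-connected component labels of a logical matrix (iterative flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          idx <- (jj - 1L) * nr + ii
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- nxt
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  lab
}

nearest_cell <- function(grid, z) {
  c(which.min(abs(grid$re - Re(z))), which.min(abs(grid$im - Im(z))))
}

#' Eigenvalue encapsulation by pseudospectral contours
#'
#' For each eigenvalue and each epsilon level, reports whether the connected
#' sublevel region (`sigma_min <= epsilon`) containing that eigenvalue also
#' contains another eigenvalue, and how many grid cells the region covers.
#' The lower the contours that already merge an eigenvalue with its
#' neighbours, the less stable the matrix and the greater its proneness to
#' transient behaviour.
#'
#' @param grid a [sigma_min_grid()] result.
#' @param levels epsilon levels to summarise; defaults to the grid's levels.
#' @return data.frame with columns eigenvalue_index, eigenvalue_re,
#'   eigenvalue_im, level, component_cells, shared (TRUE if the component
#'   contains another eigenvalue).
#' @export
contour_summary <- function(grid, levels = grid$levels) {
  floorv <- min(grid$sigma_min)
  usable <- levels >= floorv
  if (any(!usable)) {
    warning(sprintf("%d level(s) below the grid floor %.3g skipped",
                    sum(!usable), floorv))
    levels <- levels[usable]
  }
  ev <- grid$eigenvalues
  cells <- t(vapply(ev, function(z) nearest_cell(grid, z), integer(2)))
  out <- list()
  for (lv in levels) {
    lab <- label_components(grid$sigma_min <= lv)
    comp <- lab[cbind(cells[, 1], cells[, 2])]
    sizes <- tabulate(lab)
    for (k in seq_along(ev)) {
      shared <- comp[k] > 0L && any(comp[-k] == comp[k])
      out[[length(out) + 1L]] <- data.frame(
        eigenvalue_index = k, eigenvalue_re = Re(ev[k]), eigenvalue_im = Im(ev[k]),
        level = lv,
        component_cells = if (comp[k] > 0L) sizes[comp[k]] else 0L,
        shared = shared)
    }
  }
  do.call(rbind, out)
}

#' Export a pseudospectrum grid as long-format CSV
#'
#' Columns re, im, sigma_min (one row per grid point) plus a sidecar
#' `<path>.levels.csv` with the contour levels.
#'
#' @param grid a [sigma_min_grid()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pseudospectrum_csv <- function(grid, path) {
  df <- data.frame(re = rep(grid$re, times = length(grid$im)),
                   im = rep(grid$im, each = length(grid$re)),
                   sigma_min = as.vector(grid$sigma_min))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(level = grid$levels),
                   paste0(sub("\\.csv$", "", path), ".levels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
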