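#' Gaussian kernel density model over peak centers
#'
#' Bundles a terminal node's peak-center positions with a bandwidth into a
#' density model. The estimate at a point x is
#' `(1/(N h)) * sum_i K((x - x_i)/h)` with the standard Gaussian kernel
#' `K(u) = (2*pi)^(-1/2) exp(-u^2/2)`, i.e. an equally weighted mixture of
#' Gaussians centered at the observed peak centers with standard deviation
#' `h` (the bandwidth, in bp).
#'
#' @param positions Numeric vector of peak-center coordinates (bp), length
#'   >= 1; stored sorted.
#' @param bandwidth Positive smoothing scale `h` in bp.
#' @return An object of class `kde_model` with elements `x` (sorted
#'   positions), `h`, and `n`.
#' @export
#' @examples
#' m <- kde_model(c(0, 200), bandwidth = 100)
#' kde_density(m, 100)
kde_model <- function(positions, bandwidth) {
  if (!is.numeric(positions) || length(positions) < 1 || anyNA(positions)) {
    abort("`positions` must be a non-empty numeric vector without NA")
  }
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 ||
      is.na(bandwidth) || bandwidth <= 0) {
    abort("`bandwidth` must be a single positive number")
  }
  structure(list(x = sort(as.numeric(positions)),
                 h = as.numeric(bandwidth),
                 n = length(positions)),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat("Gaussian KDE model: n =", x$n, "peak centers, bandwidth =", x$h,
      "bp, span", min(x$x), "-", max(x$x), "\n")
  invisible(x)
}

#' Evaluate the kernel density estimate
#'
#' @param model A [kde_model()].
#' @param at Numeric vector of query coordinates.
#' @return Density values (per-bp probability), same length as `at`.
#' @export
kde_density <- function(model, at) {
  stopifnot(inherits(model, "kde_model"))
  u <- outer(at, model$x, "-") / model$h
  rowMeans(dnorm(u)) / model$h
}

# First derivative of the density: f'(q) = -(1/(N h^2)) sum u_i phi(u_i)
kde_gradient <- function(model, at) {
  u <- outer(at, model$x, "-") / model$h
  -rowMeans(u * dnorm(u)) / model$h^2
}

# Second derivative: f''(q) = (1/(N h^3)) sum (u_i^2 - 1) phi(u_i)
kde_curvature <- function(model, at) {
  u <- outer(at, model$x, "-") / model$h
  rowMeans((u^2 - 1) * dnorm(u)) / model$h^3
}

#' Find all local maxima and minima of a kernel density estimate
#'
#' A Gaussian mixture with equal weights has at most as many local maxima as
#' components, and when components are close relative to the bandwidth a
#' maximum must lie between their extreme locations; so hill-climbing from
#' every sample point visits every mode. From each (distinct) peak center
#' the mean-shift fixed point update
#' `x <- sum_i x_i K((x - x_i)/h) / sum_i K((x - x_i)/h)`
#' is iterated until the step falls below `tol_fix`, then the stationary
#' point is polished with Newton steps on the density gradient and
#' classified by the sign of the second derivative. Converged maxima closer
#' than `merge_tol` are merged; the unique local minimum between each
#' adjacent pair of retained maxima is then located by bisection on the
#' gradient.
#'
#' @param model A [kde_model()].
#' @param tol_fix Mean-shift convergence tolerance in bp; default `1e-3 * h`.
#' @param tol_grad Gradient tolerance for the Newton polish; default
#'   `1e-9 * dnorm(0) / h^2` (a 1e-9 relative tolerance on the natural
#'   gradient scale of a mixture with bandwidth `h`).
#' @param merge_tol Maxima closer than this are considered one mode; default
#'   `1e-2 * h`. A flat stationary point (second derivative numerically
#'   zero, as for two equal points at exactly `2h` separation) is treated as
#'   a single maximum.
#' @param max_iter Iteration cap for the mean-shift phase; on hitting it a
#'   warning is issued and the current iterate is used.
#'
#' @return An object of class `mode_set`: a list with sorted numeric vectors
#'   `maxima` and `minima` that strictly alternate, beginning and ending
#'   with a maximum (`length(minima) == length(maxima) - 1`).
#' @export
find_modes <- function(model, tol_fix = NULL, tol_grad = NULL,
                       merge_tol = NULL, max_iter = 500L) {
  stopifnot(inherits(model, "kde_model"))
  h <- model$h
  x <- model$x
  if (is.null(tol_fix)) tol_fix <- 1e-3 * h
  if (is.null(tol_grad)) tol_grad <- 1e-9 * dnorm(0) / h^2
  if (is.null(merge_tol)) merge_tol <- 1e-2 * h

  starts <- unique(x)
  if (length(starts) == 1) {
    return(new_mode_set(starts, numeric(0), model))
  }

  # mean-shift hill climb from every distinct sample point, run in parallel
  y <- starts
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    u <- outer(y, x, "-") / h
    w <- dnorm(u)
    y_new <- as.numeric(w %*% x) / rowSums(w)
    moved <- max(abs(y_new - y))
    y <- y_new
    if (moved < tol_fix) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("mean-shift did not converge in ", max_iter,
                " iterations; using current iterates"))
  }

  # Newton polish on the gradient, one stationary point at a time
  y <- vapply(y, newton_polish, numeric(1), model = model,
              tol_grad = tol_grad)

  # keep maxima (and flat degenerate points, e.g. the 2h-separated pair)
  curv_scale <- dnorm(0) / h^3
  cc <- kde_curvature(model, y)
  y <- y[cc < 1e-8 * curv_scale]
  y <- sort(y)

  # merge near-duplicates, representing each cluster by its densest member
  grp <- cumsum(c(1, diff(y) > merge_tol))
  maxima <- vapply(split(y, grp), function(g) {
    g[which.max(kde_density(model, g))]
  }, numeric(1))
  maxima <- unname(sort(maxima))

  # a genuine maximum has an uphill gradient on its left and a downhill one
  # on its right; candidates stranded on a nearly flat shoulder (where the
  # fixed-point steps stall before reaching the true mode) fail this and are
  # discarded — the mode they belong to is reached from its own members
  genuine <- vapply(maxima, function(mx) {
    (kde_gradient(model, mx - merge_tol) > 0 &&
       kde_gradient(model, mx + merge_tol) < 0) ||
      (abs(kde_gradient(model, mx)) <= tol_grad &&
         kde_curvature(model, mx) < 0)
  }, logical(1))
  maxima <- maxima[genuine]

  # bracket the unique antimode between each adjacent pair of maxima
  minima <- numeric(length(maxima) - 1L)
  if (length(maxima) > 1) {
    for (k in seq_len(length(maxima) - 1L)) {
      minima[k] <- find_antimode(model, maxima[k], maxima[k + 1L], tol_fix)
    }
  }
  new_mode_set(maxima, minima, model)
}

newton_polish <- function(y, model, tol_grad, max_iter = 50L) {
  h <- model$h
  for (i in seq_len(max_iter)) {
    g <- kde_gradient(model, y)
    if (abs(g) < tol_grad) break
    cc <- kde_curvature(model, y)
    if (!is.finite(cc) || cc == 0) break
    step <- g / cc
    if (!is.finite(step) || abs(step) > h) break  # Newton diverging; keep y
    y <- y - step
  }
  y
}

# Unique local minimum of the density strictly between two adjacent maxima:
# the gradient crosses zero from negative to positive exactly once there.
find_antimode <- function(model, a, b, eps) {
  lo <- a + eps
  hi <- b - eps
  g_lo <- kde_gradient(model, lo)
  g_hi <- kde_gradient(model, hi)
  if (g_lo < 0 && g_hi > 0) {
    return(uniroot(function(q) kde_gradient(model, q), c(lo, hi),
                   tol = .Machine$double.eps^0.75)$root)
  }
  # numerically flat shoulder: fall back to a fine grid argmin
  grid <- seq(a, b, length.out = 2001L)
  grid[which.min(kde_density(model, grid))]
}

new_mode_set <- function(maxima, minima, model) {
  structure(list(maxima = maxima, minima = minima, model = model),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode set:", length(x$maxima), "local maxima,",
      length(x$minima), "local minima\n")
  invisible(x)
}

#' @describeIn find_modes Tidy a `mode_set` into a tibble with columns
#'   `type` (`"maximum"`/`"minimum"`), `position`, and `density`.
#' @param x A `mode_set`.
#' @param ... Unused.
#' @export
tidy.mode_set <- function(x, ...) {
  pos <- c(x$maxima, x$minima)
  tibble::tibble(
    type = rep(c("maximum", "minimum"),
               c(length(x$maxima), length(x$minima))),
    position = pos,
    density = kde_density(x$model, pos)
  ) |>
    dplyr::arrange(.data$position)
}

#' Delineate modal regions around each local maximum
#'
#' The local minima partition the axis into one basin per maximum; every
#' sample point is assigned to the basin it falls in (a point lying exactly
#' on a minimum goes to the left basin). A region extends from its leftmost
#' member peak center to its rightmost, so a region with a single member has
#' width zero. A summit falling numerically outside its members' span is
#' clamped to the span.
#'
#' @param model A [kde_model()].
#' @param modes The matching [find_modes()] result.
#' @return A tibble with one row per modal region, left to right: `region`,
#'   `summit`, `left`, `right`, `n_members`, and a `members` list-column of
#'   indices into `model$x`.
#' @export
delineate_regions <- function(model, modes) {
  stopifnot(inherits(model, "kde_model"), inherits(modes, "mode_set"))
  x <- model$x
  basin <- findInterval(x, modes$minima, left.open = TRUE) + 1L
  out <- purrr::map(seq_along(modes$maxima), function(k) {
    idx <- which(basin == k)
    if (length(idx) == 0) {
      return(NULL)
    }
    left <- x[idx[1]]
    right <- x[idx[length(idx)]]
    tibble::tibble(summit = min(max(modes$maxima[k], left), right),
                   left = left, right = right,
                   n_members = length(idx), members = list(idx))
  })
  dropped <- sum(purrr::map_lgl(out, is.null))
  if (dropped > 0) {
    warn(paste0(dropped, " mode(s) had no member peak centers and were dropped"))
  }
  out |>
    purrr::list_rbind() |>
    dplyr::mutate(region = dplyr::row_number(), .before = 1)
}

#' Plot a kernel density model with its modes and member points
#'
#' @param object A [kde_model()].
#' @param modes Optionally, a precomputed [find_modes()] result.
#' @param ... Unused.
#' @return A ggplot: density curve, rug of peak centers, summits and
#'   antimodes marked.
#' @export
autoplot.kde_model <- function(object, modes = NULL, ...) {
  pad <- 3 * object$h
  grid <- seq(min(object$x) - pad, max(object$x) + pad, length.out = 512)
  d <- tibble::tibble(position = grid, density = kde_density(object, grid))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_rug(data = tibble::tibble(position = object$x),
                      ggplot2::aes(x = .data$position), inherit.aes = FALSE,
                      sides = "b", alpha = 0.5) +
    ggplot2::labs(x = "genomic position (bp)", y = "density (per bp)") +
    ggplot2::theme_minimal()
  if (!is.null(modes)) {
    md <- tidy(modes)
    p <- p + ggplot2::geom_point(data = md,
      ggplot2::aes(.data$position, .data$density, shape = .data$type),
      size = 2, colour = "firebrick")
  }
  p
}
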