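#' Analytic spherical head model
#'
#' A single homogeneous conducting sphere used as the forward model for
#' equivalent current dipole fitting and for the synthetic-EEG generator.
#' Sources are constrained to an inner "brain" sphere whose radius is a
#' fraction of the scalp radius.
#'
#' @param radius Scalp sphere radius in mm.
#' @param conductivity Homogeneous conductivity in S/m.
#' @param brain_fraction Fraction of `radius` delimiting the brain sphere;
#'   dipoles must lie strictly inside it.
#' @return An object of class `sphere_model`.
#' @export
sphere_model <- function(radius = 85, conductivity = 0.33,
                         brain_fraction = 0.95) {
  stopifnot(radius > 0, conductivity > 0,
            brain_fraction > 0, brain_fraction < 1)
  structure(list(radius = radius, conductivity = conductivity,
                 brain_fraction = brain_fraction),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf(
    "Spherical head model: R = %g mm, sigma = %g S/m, brain sphere = %g mm\n",
    x$radius, x$conductivity, x$brain_fraction * x$radius))
  invisible(x)
}

## Legendre polynomials P_n(x) and the derivative-based associated function
## sin(gamma) * P_n'(x); both advanced jointly by the usual three-term
## recurrence.  `x` may be a vector (one entry per electrode).

#' Scalp potential of a current dipole in a conducting sphere
#'
#' Potential of a point current dipole inside a homogeneous conducting
#' sphere, evaluated at electrode positions on the scalp surface, by the
#' truncated Legendre series
#' \deqn{V = \frac{1}{4\pi\sigma} \sum_{n\ge1} \frac{2n+1}{n}
#'   \frac{b^{n-1}}{R^{n+1}} [ n q_r P_n(\cos\gamma) + q_t P_n^1(\cos\gamma) ]}
#' with \eqn{b} the dipole eccentricity, \eqn{\gamma} the angle between the
#' dipole position and the electrode, and \eqn{q_r}, \eqn{q_t} the radial and
#' tangential moment components (here \eqn{P_n^1(\cos\gamma) =
#' \sin\gamma\,P_n'(\cos\gamma)}, without the Condon-Shortley phase).
#' The series is truncated when the relative contribution of a term drops
#' below `tol` (hard cap `max_terms` terms).  The returned potential is
#' mean-referenced across electrodes.
#'
#' @param r0 Dipole location, length-3 vector (mm, head frame).
#' @param q Dipole moment, length-3 vector (arbitrary consistent units).
#' @param electrodes n x 3 matrix of electrode positions on the scalp (mm).
#' @param sphere A [sphere_model()].
#' @param tol Relative truncation tolerance for the series.
#' @param max_terms Maximum series order.
#' @return Numeric vector of mean-referenced potentials, one per electrode.
#' @export
scalp_potential <- function(r0, q, electrodes, sphere = sphere_model(),
                            tol = 1e-10, max_terms = 200) {
  r0 <- as.numeric(r0); q <- as.numeric(q)
  stopifnot(length(r0) == 3, length(q) == 3)
  electrodes <- as.matrix(electrodes)
  R <- sphere$radius
  b <- sqrt(sum(r0^2))
  if (b >= R) stop("dipole location lies outside the sphere")
  ker <- .dipole_kernels(r0, electrodes, sphere, tol = tol,
                         max_terms = max_terms)
  v <- ker$G %*% q
  drop(v - mean(v))
}

## Forward basis for a dipole location: 64x3-style matrix G with V = G %*% q
## (not mean-referenced).  Shared by scalp_potential and the linear moment
## solve inside fit_dipole.
.dipole_kernels <- function(r0, electrodes, sphere, tol = 1e-10,
                            max_terms = 200) {
  R <- sphere$radius
  sig <- sphere$conductivity
  b <- sqrt(sum(r0^2))
  ne <- nrow(electrodes)
  re <- sqrt(rowSums(electrodes^2))
  ehat <- electrodes / re
  scale0 <- 1 / (4 * pi * sig)
  if (b < 1e-9) {
    ## central dipole: only the n = 1 term survives, V = 3 (q . ehat)/(4 pi
    ## sigma R^2)
    G <- 3 * scale0 / R^2 * ehat
    return(list(G = G, kR = NULL, kT = NULL))
  }
  rhat <- r0 / b
  cosg <- pmin(1, pmax(-1, ehat %*% rhat))
  cosg <- drop(cosg)
  sing <- sqrt(pmax(0, 1 - cosg^2))
  ## tangential unit vector at each electrode, in the (r0, electrode) plane
  that <- ehat - outer(cosg, rhat)
  tn <- sqrt(rowSums(that^2))
  ok <- tn > 1e-12
  that[ok, ] <- that[ok, ] / tn[ok]
  that[!ok, ] <- 0

  ## recurrences: P_n and Q_n = sin(g) P_n'(cos g)
  Pm1 <- rep(1, ne)          # P_0
  P <- cosg                  # P_1
  Q <- sing                  # sin * P_1' = sin
  kR <- numeric(ne)
  kT <- numeric(ne)
  ratio <- b / R
  pref <- 1 / R^2            # b^{n-1}/R^{n+1} at n = 1
  for (n in seq_len(max_terms)) {
    cR <- (2 * n + 1) / n * pref * n       # multiplies q_r P_n
    cT <- (2 * n + 1) / n * pref           # multiplies q_t Q_n
    dR <- cR * P
    dT <- cT * Q
    kR <- kR + dR
    kT <- kT + dT
    if (n >= 2 && n %% 4 == 0) {
      rel <- max(abs(dR), abs(dT)) /
        max(max(abs(kR)), max(abs(kT)), .Machine$double.xmin)
      if (rel < tol) break
    }
    ## advance to n + 1
    Pp1 <- ((2 * n + 1) * cosg * P - n * Pm1) / (n + 1)
    ## (1-x^2) P_{n+1}'(x) = (n+1) (P_n - x P_{n+1});  Q = sin * P'
    Qp1 <- ifelse(sing > 1e-12,
                  (n + 1) * (P - cosg * Pp1) / sing, 0)
    Pm1 <- P; P <- Pp1; Q <- Qp1
    pref <- pref * ratio
  }
  kR <- scale0 * kR
  kT <- scale0 * kT
  G <- kR * matrix(rhat, ne, 3, byrow = TRUE) + kT * that
  list(G = G, kR = kR, kT = kT)
}

#' Precomputed dipole search grid
#'
#' Builds the deterministic coarse grid (default 5 mm spacing) inside the
#' brain sphere used to seed the nonlinear dipole search, together with the
#' forward basis at every grid node, so repeated fits against the same
#' electrode layout are cheap.
#'
#' @param electrodes n x 3 electrode matrix (mm).
#' @param sphere A [sphere_model()].
#' @param spacing Grid spacing in mm.
#' @param max_terms Series order used at grid stage (refinement always uses
#'   the full-accuracy series).
#' @return An object of class `dipole_grid`.
#' @export
dipole_grid <- function(electrodes, sphere = sphere_model(), spacing = 5,
                        max_terms = 60) {
  electrodes <- as.matrix(electrodes)
  rb <- sphere$brain_fraction * sphere$radius
  ax <- seq(-rb, rb, by = spacing)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- rowSums(pts^2) <= (rb - spacing / 2)^2
  pts <- pts[keep, , drop = FALSE]
  ## deterministic ordering: lexicographic in (x, y, z)
  ord <- order(pts[, 1], pts[, 2], pts[, 3])
  pts <- pts[ord, , drop = FALSE]
  gk <- .dipole_kernels_grid(pts, electrodes, sphere, max_terms = max_terms)
  structure(list(points = pts, Gx = gk$Gx, Gy = gk$Gy, Gz = gk$Gz,
                 electrodes = electrodes, sphere = sphere,
                 spacing = spacing),
            class = "dipole_grid")
}

## Vectorised forward basis over many candidate locations at once: returns
## the three per-moment basis matrices (np x ne, mean-referenced across
## electrodes) used by the grid stage of fit_dipole.
.dipole_kernels_grid <- function(points, electrodes, sphere, max_terms = 60) {
  R <- sphere$radius
  sig <- sphere$conductivity
  np <- nrow(points)
  ne <- nrow(electrodes)
  re <- sqrt(rowSums(electrodes^2))
  ehat <- electrodes / re
  b <- sqrt(rowSums(points^2))
  b <- pmax(b, 1e-9)
  rhat <- points / b
  cosg <- rhat %*% t(ehat)
  cosg <- pmin(1, pmax(-1, cosg))
  sing <- sqrt(pmax(0, 1 - cosg^2))
  thx <- matrix(ehat[, 1], np, ne, byrow = TRUE) - cosg * rhat[, 1]
  thy <- matrix(ehat[, 2], np, ne, byrow = TRUE) - cosg * rhat[, 2]
  thz <- matrix(ehat[, 3], np, ne, byrow = TRUE) - cosg * rhat[, 3]
  tn <- sqrt(thx^2 + thy^2 + thz^2)
  tn[tn < 1e-12] <- Inf
  thx <- thx / tn; thy <- thy / tn; thz <- thz / tn

  Pm1 <- matrix(1, np, ne)
  P <- cosg
  Q <- sing
  kR <- matrix(0, np, ne)
  kT <- matrix(0, np, ne)
  pref <- rep(1 / R^2, np)
  ratio <- b / R
  small <- sing < 1e-12
  for (n in seq_len(max_terms)) {
    cc <- (2 * n + 1) / n * pref
    kR <- kR + (cc * n) * P
    kT <- kT + cc * Q
    Pp1 <- ((2 * n + 1) * cosg * P - n * Pm1) / (n + 1)
    Qp1 <- (n + 1) * (P - cosg * Pp1) / sing
    Qp1[small] <- 0
    Pm1 <- P; P <- Pp1; Q <- Qp1
    pref <- pref * ratio
  }
  scale0 <- 1 / (4 * pi * sig)
  kR <- scale0 * kR
  kT <- scale0 * kT
  Gx <- kR * rhat[, 1] + kT * thx
  Gy <- kR * rhat[, 2] + kT * thy
  Gz <- kR * rhat[, 3] + kT * thz
  ## mean-reference across electrodes (rows are locations)
  Gx <- Gx - rowMeans(Gx)
  Gy <- Gy - rowMeans(Gy)
  Gz <- Gz - rowMeans(Gz)
  list(Gx = Gx, Gy = Gy, Gz = Gz)
}

## residual variance of the best linear moment fit at one location
.dipole_rv_at <- function(r0, topo, electrodes, sphere) {
  G <- .dipole_kernels(r0, electrodes, sphere)$G
  G <- sweep(G, 2, colMeans(G))
  t0 <- topo - mean(topo)
  fit <- stats::lm.fit(G, t0)
  ss_tot <- sum(t0^2)
  rv <- sum(fit$residuals^2) / ss_tot
  list(rv = rv, q = fit$coefficients)
}

#' Fit an equivalent current dipole to a scalp topography
#'
#' Nonlinear least-squares search for the dipole location (the moment enters
#' the forward model linearly and is solved in closed form at each candidate
#' location).  A deterministic coarse grid inside the brain sphere seeds
#' `n_restarts` local refinements; the solution with the lowest residual
#' variance is returned, ties broken by lexicographic location.
#'
#' @param topography Numeric vector, one value per electrode (any reference;
#'   internally mean-referenced).
#' @param electrodes n x 3 electrode matrix (mm).
#' @param sphere A [sphere_model()].
#' @param n_restarts Number of grid seeds refined by local optimisation.
#' @param grid Optional precomputed [dipole_grid()] (rebuilt otherwise).
#' @return An object of class `dipole_fit` with elements `location`,
#'   `moment`, `rv` (residual variance, fraction of scalp-map variance not
#'   explained by the dipole projection).
#' @export
fit_dipole <- function(topography, electrodes, sphere = sphere_model(),
                       n_restarts = 5, grid = NULL) {
  electrodes <- as.matrix(electrodes)
  topography <- as.numeric(topography)
  stopifnot(length(topography) == nrow(electrodes))
  if (nrow(electrodes) < 8)
    stop("dipole fitting requires at least 8 electrodes")
  if (all(abs(topography) < .Machine$double.eps))
    stop("all-zero topography")
  if (is.null(grid)) grid <- .grid_cache(electrodes, sphere)
  t0 <- topography - mean(topography)
  ss_tot <- sum(t0^2)

  ## vectorised grid stage: for every node solve the 3x3 normal equations
  bx <- drop(grid$Gx %*% t0)
  by <- drop(grid$Gy %*% t0)
  bz <- drop(grid$Gz %*% t0)
  a11 <- rowSums(grid$Gx * grid$Gx)
  a22 <- rowSums(grid$Gy * grid$Gy)
  a33 <- rowSums(grid$Gz * grid$Gz)
  a12 <- rowSums(grid$Gx * grid$Gy)
  a13 <- rowSums(grid$Gx * grid$Gz)
  a23 <- rowSums(grid$Gy * grid$Gz)
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  det[abs(det) < .Machine$double.xmin] <- NA
  qx <- (bx * (a22 * a33 - a23^2) - a12 * (by * a33 - a23 * bz) +
           a13 * (by * a23 - a22 * bz)) / det
  qy <- (a11 * (by * a33 - a23 * bz) - bx * (a12 * a33 - a23 * a13) +
           a13 * (a12 * bz - by * a13)) / det
  qz <- (a11 * (a22 * bz - by * a23) - a12 * (a12 * bz - by * a13) +
           bx * (a12 * a23 - a22 * a13)) / det
  explained <- qx * bx + qy * by + qz * bz
  rv_grid <- 1 - explained / ss_tot
  rv_grid[is.na(rv_grid)] <- Inf

  seeds <- order(rv_grid)[seq_len(min(n_restarts, length(rv_grid)))]
  rb <- sphere$brain_fraction * sphere$radius
  obj <- function(p) {
    r <- sqrt(sum(p^2))
    if (r >= rb) p <- p * ((rb - 1e-6) / r)
    .dipole_rv_at(p, topography, electrodes, sphere)$rv
  }
  best <- NULL
  for (s in seeds) {
    if (!is.null(best) && best$rv < 1e-9) break  # already an exact fit
    p0 <- grid$points[s, ]
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 150, reltol = 1e-9))
    p <- opt$par
    r <- sqrt(sum(p^2))
    if (r >= rb) p <- p * ((rb - 1e-6) / r)
    sol <- .dipole_rv_at(p, topography, electrodes, sphere)
    cand <- list(location = unname(p), moment = unname(sol$q), rv = sol$rv)
    if (is.null(best) || cand$rv < best$rv - 1e-15 ||
        (abs(cand$rv - best$rv) <= 1e-15 &&
         .lex_lt(cand$location, best$location)))
      best <- cand
  }
  best$rv <- max(0, min(1, best$rv))
  structure(c(best, list(sphere = sphere, n_electrodes = nrow(electrodes))),
            class = "dipole_fit")
}

.lex_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

## cache grids per electrode layout within a session
.grid_env <- new.env(parent = emptyenv())
.grid_cache <- function(electrodes, sphere) {
  key <- paste0(nrow(electrodes), "_",
                format(sum(electrodes) + sum(electrodes^2), digits = 15),
                "_", sphere$radius, "_", sphere$brain_fraction)
  g <- .grid_env[[key]]
  if (is.null(g)) {
    g <- dipole_grid(electrodes, sphere)
    .grid_env[[key]] <- g
  }
  g
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf(
    "Equivalent current dipole: location (%.1f, %.1f, %.1f) mm, RV = %.3g\n",
    x$location[1], x$location[2], x$location[3], x$rv))
  invisible(x)
}

#' Quasi-uniform scalp electrode layout
#'
#' Deterministic Fibonacci-lattice electrode positions covering the upper
#' part of the scalp sphere (down to a configurable inferior cutoff),
#' mimicking a whole-head EEG cap.
#'
#' @param n Number of electrodes.
#' @param sphere A [sphere_model()].
#' @param z_min Lowest electrode height as a fraction of the radius
#'   (negative values extend below the equator).
#' @return n x 3 matrix of positions (mm) with row names `E001`...
#' @export
electrode_layout <- function(n = 64, sphere = sphere_model(), z_min = -0.25) {
  R <- sphere$radius
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - z_min) * i / n        # from ~1 down to z_min
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  pos <- R * cbind(x = s * cos(phi), y = s * sin(phi), z = z)
  rownames(pos) <- sprintf("E%03d", seq_len(n))
  pos
}
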