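#' Fit a maximum-likelihood mixture of ICA models
#'
#' Fits `M` complete ICA models to multichannel data by maximum likelihood.
#' Each model `h` has an unmixing matrix `W_h`, a bias `c_h`, and an adaptive
#' generalized-Gaussian density per source,
#' \deqn{\log q(s) = \log\frac{\rho}{2\beta\Gamma(1/\rho)} - |s/\beta|^\rho,}
#' and the models compete for samples through posterior responsibilities.
#' One iteration alternates (a) per-sample responsibilities
#' \eqn{\gamma_h(t) \propto \pi_h \exp L_h(x_t)} with
#' \eqn{L_h(x_t) = \log|\det W_h| + \sum_i \log q(s_{hi}(t))};
#' (b) a responsibility-weighted natural-gradient update
#' \eqn{\Delta W_h \propto (I - E_\gamma[\varphi(s)s^\top])W_h} with score
#' \eqn{\varphi_i(s) = \rho_i \mathrm{sign}(s)|s/\beta_i|^{\rho_i-1}/\beta_i};
#' (c) the closed-form scale update
#' \eqn{\beta_i = (\rho_i E_\gamma|s_i|^{\rho_i})^{1/\rho_i}} and a bounded
#' line-search update of each shape \eqn{\rho_i}; and (d) prior update
#' \eqn{\pi_h = \mathrm{mean}_t\,\gamma_h(t)}.  The learning rate is annealed
#' and halved whenever the total log-likelihood decreases; ten consecutive
#' failures abort the fit.
#'
#' Data are centered, then PCA-reduced and whitened to `n_components`
#' dimensions before fitting; scalp maps are mapped back through the
#' reduction (see [scalp_maps()]).
#'
#' @param x Numeric matrix, channels x samples, or an `eeg_recording`.
#' @param M Number of mixture models.
#' @param n_components Retained PCA dimensions (default `min(16, channels)`).
#' @param max_iter,tol Iteration cap and relative log-likelihood convergence
#'   tolerance.
#' @param seed Integer seed controlling initialisation (and subsampling).
#' @param max_samples If non-`NULL` and the data are longer, fitting uses
#'   this many evenly spaced samples (classification and prediction always
#'   use the samples given to them).
#' @param rho_every Update the density shapes every this many iterations.
#' @param rho_range Allowed range for the generalized-Gaussian shape.
#' @param lrate Initial natural-gradient learning rate.
#' @param n_scale Number of scale components per source density (a
#'   mixture of generalized Gaussians sharing the shape but with their own
#'   scales and weights).  The default 1 is a single generalized Gaussian;
#'   3 lets each model absorb state-dependent source variance (bursts,
#'   desynchronization) inside its densities, so the model competition is
#'   driven by mixing geometry rather than amplitude state.
#' @param init Initialisation: `"blocks"` (default; a shared single-model
#'   warm start, then each model refined on one cluster of data blocks
#'   grouped by their second-order structure before the joint
#'   competition), `"shared"` (perturbed copies of the shared warm
#'   start), or `"random"` (independent random orthogonal starts).
#' @param n_restarts Number of independent restarts (initialisation seeds
#'   derived from `seed`); the fit with the highest final log-likelihood
#'   is kept.  Occasional restarts converge to clearly inferior optima --
#'   the likelihood gap identifies them reliably -- so 2-3 restarts are
#'   recommended for mixture fits on real-length recordings.
#' @param refine_iter Iterations of the per-cluster refinement stage of
#'   the `"blocks"` initialisation.
#' @param joint_iter Iterations of joint unmixing competition after a
#'   successful block-seeded initialisation.  The default 0 skips the
#'   post-seeding competition entirely (a density-and-prior consolidation
#'   phase with frozen unmixing always follows): protocols whose
#'   amplitude states (task/pause, bursts) carry more likelihood than the
#'   spatial regime difference can otherwise pull the competition away
#'   from the regime split.  Unseeded fits always run the full
#'   competition to `max_iter`.
#' @param verbose Print progress.
#' @return An object of class `mixica`: list of `models` (each with `W`,
#'   `bias`, `rho`, `beta`), `priors`, `loglik_trace`, `whitening`,
#'   `dewhitening`, `center`, `n_components`, `seed`.
#' @seealso [model_probability()], [classify_trials_by_model()],
#'   [scalp_maps()], [amari_index()]
#' @export
mixica <- function(x, M = 2, n_components = NULL, max_iter = 300,
                   tol = 1e-7, seed = 1, max_samples = NULL,
                   rho_every = 5, rho_range = c(0.5, 4), lrate = 0.1,
                   n_scale = 1L,
                   init = c("blocks", "shared", "random"),
                   refine_iter = 120, joint_iter = 0,
                   n_restarts = 1L,
                   verbose = FALSE) {
  init <- match.arg(init)
  if (inherits(x, "eeg_recording")) x <- x$eeg
  x <- as.matrix(x)
  nch <- nrow(x)
  if (is.null(n_components)) n_components <- min(16L, nch)
  n <- as.integer(n_components)
  stopifnot(M >= 1, n >= 2, n <= nch)

  center <- rowMeans(x)
  xc <- x - center
  ## PCA whitening on the full data
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(n)], .Machine$double.eps)
  K <- diag(1 / sqrt(ev), n) %*% t(eg$vectors[, seq_len(n), drop = FALSE])
  Kinv <- eg$vectors[, seq_len(n), drop = FALSE] %*% diag(sqrt(ev), n)
  y <- K %*% xc
  rm(xc, cv)
  Tn <- ncol(y)
  if (!is.null(max_samples) && Tn > max_samples) {
    idx <- unique(round(seq(1, Tn, length.out = max_samples)))
    yf <- y[, idx, drop = FALSE]
  } else yf <- y
  Tf <- ncol(yf)
  if (Tf < 20 * n^2)
    warning("fewer than 20 * n^2 samples; mixture ICA may be unstable")

  C <- as.integer(n_scale)
  stopifnot(C >= 1)
  ## stagger the initial scales so the mixture components differentiate
  beta0 <- matrix(rep(2^(seq_len(C) - (C + 1) / 2), each = n), n, C)

  ## block features for the seeded initialisation (deterministic; shared
  ## by all restarts)
  bl <- 4096L
  nb <- floor(Tn / bl)
  feat <- NULL
  if (M > 1 && init == "blocks" && nb >= 4 * M) {
    feat <- matrix(0, nb, n * (n + 1) / 2)
    ut <- upper.tri(diag(n), diag = TRUE)
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * bl + 1):(b * bl)
      Cb <- tcrossprod(y[, idx]) / bl
      feat[b, ] <- Cb[ut]
    }
  }

  one_fit <- function(rseed) {
    set.seed(rseed)
    models <- lapply(seq_len(M), function(h) {
      W <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
      list(W = W, bias = rep(0, n), rho = rep(1.5, n), beta = beta0,
           wmix = matrix(1 / C, n, C))
    })
    priors <- rep(1 / M, M)
    seeded <- FALSE
    if (M > 1 && init != "random") {
      ## warm start: fit one shared model first; specialisation from a
      ## common solution is much faster than from independent random
      ## starts
      shared <- .mixica_core(models[1], 1, yf,
                             max_iter = min(max_iter, 120),
                             tol = max(tol, 1e-6), lrate = lrate,
                             rho_every = rho_every, rho_range = rho_range,
                             verbose = FALSE)
      base <- shared$models[[1]]
      models <- lapply(seq_len(M), function(h) {
        pert <- diag(n) + 0.05 * matrix(stats::rnorm(n * n), n, n)
        list(W = pert %*% base$W, bias = base$bias, rho = base$rho,
             beta = base$beta, wmix = base$wmix)
      })
      if (!is.null(feat)) {
        ## seed the competition from an unsupervised segmentation:
        ## cluster the data blocks by their second-order structure and
        ## refine a copy of the shared model on each cluster's samples
        km <- stats::kmeans(feat, M, nstart = 10, iter.max = 50)
        sizes <- as.vector(table(factor(km$cluster, seq_len(M))))
        if (min(sizes) * bl >= max(10 * n^2, 2 * bl)) {
          for (h in seq_len(M)) {
            hb <- which(km$cluster == h)
            ## state-balanced refinement: protocols often carry a
            ## second, amplitude-state nonstationarity (task versus
            ## pause depth, movement bursts); sub-clustering this
            ## model's blocks and drawing equally from each sub-state
            ## keeps the refined model from fitting one state better
            ## than its competitor fits it, which would bias later
            ## segment classification
            sub <- if (length(hb) >= 8) {
              ks <- stats::kmeans(feat[hb, , drop = FALSE], 2,
                                  nstart = 5, iter.max = 50)
              split(hb, ks$cluster)
            } else list(hb)
            per_state <- max(1L, (60000L %/% bl) %/% length(sub))
            use <- unlist(lapply(sub, function(b) {
              if (length(b) > per_state)
                b[round(seq(1, length(b), length.out = per_state))]
              else b
            }))
            cols <- which(rep(km$cluster, each = bl) == h &
                            rep(seq_len(nb) %in% use, each = bl))
            ref <- .mixica_core(list(base), 1, y[, cols, drop = FALSE],
                                max_iter = refine_iter, tol = 1e-7,
                                lrate = lrate, rho_every = rho_every,
                                rho_range = rho_range, verbose = FALSE)
            models[[h]] <- ref$models[[1]]
          }
          priors <- sizes / sum(sizes)
          seeded <- TRUE
        }
      }
    }

    ## the joint competition phase consolidates priors and densities;
    ## when the models were seeded from a data segmentation it is kept
    ## short, so the specialised solutions are refined, not re-derived
    joint_cap <- if (seeded) min(joint_iter, max_iter) else max_iter
    fit <- .mixica_core(models, priors, yf, max_iter = joint_cap,
                        tol = tol, lrate = lrate, rho_every = rho_every,
                        rho_range = rho_range, verbose = verbose)
    if (seeded) {
      ## density/prior consolidation with the unmixing geometry frozen:
      ## equalises how well each model's densities fit the shared
      ## amplitude states (the per-cluster refinement exposes the models
      ## to them unevenly), without any risk of abandoning the split
      fit <- .mixica_core(fit$models, fit$priors, yf,
                          max_iter = max(joint_iter, 60), tol = tol,
                          lrate = lrate,
                          rho_every = max(1, rho_every %/% 2),
                          rho_range = rho_range, verbose = verbose,
                          update_W = FALSE)
    }
    fit
  }

  ## independent restarts; keep the highest final log-likelihood (an
  ## occasional restart converges to a clearly inferior optimum)
  fit <- NULL
  for (r in seq_len(max(1L, as.integer(n_restarts)))) {
    cand <- one_fit(seed + 977L * (r - 1L))
    if (is.null(fit) ||
        utils::tail(cand$trace, 1) > utils::tail(fit$trace, 1))
      fit <- cand
  }

  structure(list(models = fit$models, priors = fit$priors,
                 loglik_trace = fit$trace,
                 whitening = K, dewhitening = Kinv, center = center,
                 n_components = n, M = M, seed = seed,
                 n_samples_fit = Tf, converged = fit$converged),
            class = "mixica")
}

## The learning loop: natural-gradient mixture ICA on whitened data yf.
## update_W = FALSE freezes the unmixing matrices and biases (density and
## prior consolidation only).
.mixica_core <- function(models, priors, yf, max_iter, tol, lrate,
                         rho_every, rho_range, verbose,
                         update_W = TRUE) {
  M <- length(models)
  n <- nrow(yf)
  Tf <- ncol(yf)
  if (length(priors) != M) priors <- rep(1 / M, M)
  lr <- lrate
  ll_prev <- -Inf
  trace <- numeric(0)
  fails <- 0
  still <- 0
  saved <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    st <- .mixica_estep(models, priors, yf)
    ll <- st$loglik
    if (!is.finite(ll) || ll < ll_prev - 1e-8 * Tf) {
      ## reject the step: restore, halve the rate
      fails <- fails + 1
      if (fails >= 10)
        stop(sprintf(
          "mixture ICA failed to increase the likelihood 10 times in a row (iter %d, loglik %g)",
          iter, ll))
      if (!is.null(saved)) {
        models <- saved$models; priors <- saved$priors
      }
      lr <- lr / 2
      next
    }
    fails <- 0
    trace <- c(trace, ll)
    ## require a persistent plateau before declaring convergence
    still <- if (is.finite(ll_prev) &&
                 abs(ll - ll_prev) < tol * abs(ll_prev)) still + 1 else 0
    ll_prev <- ll
    saved <- list(models = models, priors = priors)
    if (still >= 3 && iter > 30) break
    if (verbose && iter %% 10 == 0)
      message(sprintf("iter %4d  loglik %.6g  lr %.3g", iter, ll, lr))

    ## M-step; a mild prior floor keeps a model from shrinking onto a
    ## small outlier niche (e.g. blink bursts) before it can specialise
    priors <- pmax(rowMeans(st$gamma), 0.2 / M)
    priors <- priors / sum(priors)
    upd_rho <- (iter %% rho_every == 0)
    for (h in seq_len(M)) {
      g <- st$gamma[h, ]
      wsum <- sum(g)
      if (wsum < n) next
      w <- g / wsum
      S <- st$S[[h]]
      phi <- st$phi[[h]]
      if (update_W) {
      Sw <- S * rep(w, each = n)
      D <- diag(n) - tcrossprod(phi, Sw)     # relative-gradient direction
      ## Newton-type preconditioning in relative coordinates:
      ## kappa_i = E[phi_i^2], sigma2_i = E[s_i^2],
      ## zeta_i = E[(phi_i s_i)^2] - 1 (via integration by parts)
      sigma2 <- drop((S * S) %*% w)
      kappa <- drop((phi * phi) %*% w)
      zeta <- drop(((phi * S)^2) %*% w) - 1
      B <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        dn <- kappa[i] * kappa[j] * sigma2[i] * sigma2[j] - 1
        if (is.finite(dn) && dn > 0.1) {
          B[i, j] <- (kappa[j] * sigma2[i] * D[i, j] - D[j, i]) / dn
          B[j, i] <- (kappa[i] * sigma2[j] * D[j, i] - D[i, j]) / dn
        } else {
          B[i, j] <- D[i, j]
          B[j, i] <- D[j, i]
        }
      }
      diag(B) <- ifelse(is.finite(zeta) & zeta > 0.1,
                        diag(D) / zeta, diag(D))
      models[[h]]$W <- models[[h]]$W + lr * B %*% models[[h]]$W
      wmean <- drop(yf %*% w)
      models[[h]]$bias <- models[[h]]$bias +
        lr * (wmean - models[[h]]$bias)
      }
      ## density updates on current sources
      beta <- as.matrix(models[[h]]$beta)
      wmix <- as.matrix(models[[h]]$wmix)
      C <- ncol(beta)
      rho <- models[[h]]$rho
      ## responsibility-weighted moments per scale component:
      ## sum_t w_t r_c |s|^rho = beta_c^rho * (P_c %*% w)
      den <- matrix(0, n, C)
      num <- matrix(0, n, C)
      for (cc in seq_len(C)) {
        pcw <- drop(st$P[[h]][[cc]] %*% w)
        den[, cc] <- if (C == 1) 1 else drop(st$R[[h]][[cc]] %*% w)
        num[, cc] <- exp(rho * log(beta[, cc])) * pcw
      }
      den <- pmax(den, 1e-8)
      beta <- exp(log(rho * num / den) / rho)
      beta <- pmax(beta, 1e-6)
      wmix <- den / rowSums(den)
      wmix <- pmax(wmix, 1e-3)
      wmix <- wmix / rowSums(wmix)
      if (upd_rho) {
        ## shape update on a subsample, profiling the scales per candidate
        sub <- if (ncol(S) > 20000)
          round(seq(1, ncol(S), length.out = 20000)) else seq_len(ncol(S))
        ws <- w[sub]; ws <- ws / sum(ws)
        Sa <- abs(S[, sub, drop = FALSE])
        la <- log(Sa + 1e-300)
        for (i in seq_len(n)) {
          ri <- if (C == 1) matrix(1, 1, length(sub)) else
            do.call(rbind, lapply(st$R[[h]], function(m) m[i, sub]))
          omega <- drop(ri %*% ws)
          omega <- omega / sum(omega)
          lai <- la[i, ]
          prof <- function(r) {
            val <- 0
            for (cc in seq_len(C)) {
              m_cr <- sum(ws * ri[cc, ] * exp(r * lai)) /
                max(sum(ws * ri[cc, ]), 1e-12)
              bstar <- (r * m_cr)^(1 / r)
              val <- val + omega[cc] *
                (log(r) - log(2 * bstar) - lgamma(1 / r) - 1 / r)
            }
            val
          }
          opt <- stats::optimize(prof, rho_range, maximum = TRUE,
                                 tol = 1e-3)
          rnew <- opt$maximum
          models[[h]]$rho[i] <- rnew
          for (cc in seq_len(C)) {
            m_cr <- sum(ws * ri[cc, ] * exp(rnew * lai)) /
              max(sum(ws * ri[cc, ]), 1e-12)
            beta[i, cc] <- (rnew * m_cr)^(1 / rnew)
          }
        }
      }
      models[[h]]$beta <- beta
      models[[h]]$wmix <- wmix
    }
    lr <- min(lr * 1.05, 0.4)
  }
  list(models = models, priors = priors, trace = trace,
       converged = iter < max_iter)
}

## E-step quantities for data y (n x T).  Each source density is a mixture
## of C generalized Gaussians sharing the shape rho_i but with their own
## scales beta_ic and weights wmix_ic (C = 1 reduces to a single
## generalized Gaussian).  Returns per model: sources S, score phi
## (-dlogq/ds), per-sample log-likelihoods LA, scale responsibilities R
## and the products P = R * |s/beta|^rho needed by the scale updates,
## model responsibilities gamma, and the total log-likelihood.
.mixica_estep <- function(models, priors, y, keep_scales = TRUE) {
  M <- length(models)
  n <- nrow(y)
  Tn <- ncol(y)
  S <- vector("list", M)
  PHI <- vector("list", M)
  R <- vector("list", M)
  P <- vector("list", M)
  LA <- matrix(0, M, Tn)
  for (h in seq_len(M)) {
    m <- models[[h]]
    beta <- as.matrix(m$beta)          # n x C
    wmix <- as.matrix(m$wmix)
    C <- ncol(beta)
    Sh <- m$W %*% (y - m$bias)
    la <- log(abs(Sh) + 1e-300)
    lconst <- log(wmix) + log(m$rho) - log(2 * beta) - lgamma(1 / m$rho)
    if (!keep_scales) {
      ## light path (prediction): running log-sum-exp over the scale
      ## components, no score or responsibilities kept
      lq <- lconst[, 1] - exp(m$rho * (la - log(beta[, 1])))
      if (C > 1) for (cc in 2:C) {
        lgc <- lconst[, cc] - exp(m$rho * (la - log(beta[, cc])))
        mxs <- pmax(lq, lgc)
        lq <- mxs + log(exp(lq - mxs) + exp(lgc - mxs))
      }
    } else {
      lg <- vector("list", C)
      t1 <- vector("list", C)
      for (cc in seq_len(C)) {
        t1[[cc]] <- exp(m$rho * (la - log(beta[, cc])))
        lg[[cc]] <- lconst[, cc] - t1[[cc]]
      }
      if (C == 1) {
        lq <- lg[[1]]
        Rh <- NULL
        Ph <- list(t1[[1]])
        phi <- m$rho * t1[[1]] / Sh
      } else {
        mxs <- lg[[1]]
        for (cc in 2:C) mxs <- pmax(mxs, lg[[cc]])
        se <- exp(lg[[1]] - mxs)
        for (cc in 2:C) se <- se + exp(lg[[cc]] - mxs)
        lq <- mxs + log(se)
        Rh <- lapply(seq_len(C), function(cc) exp(lg[[cc]] - lq))
        phi <- Rh[[1]] * t1[[1]]
        for (cc in 2:C) phi <- phi + Rh[[cc]] * t1[[cc]]
        phi <- m$rho * phi / Sh
        Ph <- lapply(seq_len(C), function(cc) Rh[[cc]] * t1[[cc]])
      }
      phi[!is.finite(phi)] <- 0
      PHI[[h]] <- phi
      R[[h]] <- Rh
      P[[h]] <- Ph
    }
    ld <- determinant(m$W, logarithm = TRUE)$modulus
    LA[h, ] <- as.numeric(ld) + .colSums(lq, n, Tn)
    S[[h]] <- Sh
  }
  lp <- LA + log(priors)
  mx <- lp[1, ]
  if (M > 1) for (h in 2:M) mx <- pmax(mx, lp[h, ])
  es <- exp(lp - rep(mx, each = M))
  cs <- .colSums(es, M, Tn)
  lse <- mx + log(cs)
  gamma <- es / rep(cs, each = M)
  list(S = S, phi = PHI, R = R, P = P, LA = LA, gamma = gamma,
       loglik = sum(lse))
}

#' @export
print.mixica <- function(x, ...) {
  cat(sprintf("Mixture ICA fit: %d model%s, %d components, %d samples\n",
              x$M, if (x$M > 1) "s" else "", x$n_components, x$n_samples_fit))
  cat(sprintf("  priors: %s\n", paste(sprintf("%.3f", x$priors),
                                      collapse = " ")))
  cat(sprintf("  final log-likelihood: %.6g (%d accepted iterations)\n",
              utils::tail(x$loglik_trace, 1), length(x$loglik_trace)))
  invisible(x)
}

#' @export
summary.mixica <- function(object, ...) {
  rho <- sapply(object$models, function(m) m$rho)
  out <- list(M = object$M, n_components = object$n_components,
              priors = object$priors,
              rho_range = range(rho),
              loglik = utils::tail(object$loglik_trace, 1),
              iterations = length(object$loglik_trace),
              converged = object$converged)
  class(out) <- "summary.mixica"
  out
}

#' @export
print.summary.mixica <- function(x, ...) {
  cat(sprintf("Mixture ICA: M = %d, n = %d, %s after %d iterations\n",
              x$M, x$n_components,
              if (x$converged) "converged" else "iteration cap reached",
              x$iterations))
  cat(sprintf("  priors: %s\n", paste(sprintf("%.3f", x$priors),
                                      collapse = " ")))
  cat(sprintf("  source shape parameters in [%.2f, %.2f]\n",
              x$rho_range[1], x$rho_range[2]))
  cat(sprintf("  log-likelihood: %.6g\n", x$loglik))
  invisible(x)
}

#' @export
coef.mixica <- function(object, ...) {
  lapply(object$models, function(m) m$W)
}

#' @export
logLik.mixica <- function(object, ...) {
  ll <- utils::tail(object$loglik_trace, 1)
  attr(ll, "df") <- object$M *
    (object$n_components^2 + 3 * object$n_components) + object$M - 1
  class(ll) <- "logLik"
  ll
}

## internal: whiten new data with the stored reduction
.mixica_project <- function(object, x) {
  if (inherits(x, "eeg_recording")) x <- x$eeg
  object$whitening %*% (as.matrix(x) - object$center)
}

#' Predict responsibilities or sources from a mixture ICA fit
#'
#' @param object A [mixica()] fit.
#' @param newdata Channels x samples matrix (original channel space).
#' @param type `"responsibility"` for per-sample posterior model
#'   probabilities (M x samples), `"loglik"` for per-sample per-model
#'   log-likelihoods, `"sources"` for the source activations of each model.
#' @param ... Unused.
#' @export
predict.mixica <- function(object, newdata,
                           type = c("responsibility", "loglik", "sources"),
                           ...) {
  type <- match.arg(type)
  y <- .mixica_project(object, newdata)
  st <- .mixica_estep(object$models, object$priors, y, keep_scales = FALSE)
  switch(type,
         responsibility = st$gamma,
         loglik = st$LA,
         sources = st$S)
}

#' Posterior model probability of a data segment
#'
#' Probability, on a 0-1 scale, that each mixture model generated the given
#' segment: the softmax of per-model prior-weighted total log-likelihood,
#' \eqn{p_h \propto \pi_h \exp \sum_{t} L_h(x_t)}, computed in the log
#' domain.
#'
#' @param object A [mixica()] fit.
#' @param segment Channels x samples matrix (original channel space).
#' @return Numeric vector of length M summing to 1.
#' @export
model_probability <- function(object, segment) {
  stopifnot(inherits(object, "mixica"))
  y <- .mixica_project(object, segment)
  st <- .mixica_estep(object$models, object$priors, y, keep_scales = FALSE)
  lp <- rowSums(st$LA) + log(object$priors)
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Scalp maps of a mixture ICA fit
#'
#' Columns of each model's mixing matrix mapped back through the PCA
#' reduction: channels x components, one matrix per model.
#' @param object A [mixica()] fit.
#' @export
scalp_maps <- function(object) {
  stopifnot(inherits(object, "mixica"))
  lapply(object$models, function(m) object$dewhitening %*% solve(m$W))
}

#' Classify trials by mixture-model fit
#'
#' Computes, per trial, the posterior model probability over the trial's
#' samples and classifies the trial's joint (knee / ankle).  Two decision
#' rules are provided.  The plain rule assigns each trial to its
#' highest-posterior model and maps models to joints by the assignment
#' that maximises agreement over all trials (best of the M! mappings).
#' The calibrated rule (default, for `M = 2`) thresholds the per-trial
#' mean log-likelihood ratio at the cut maximising agreement: a constant
#' per-sample fit offset between two separately refined models is not
#' identifiable from the mixture priors and would otherwise swamp the
#' regime evidence of low-amplitude (desynchronized) trials, so the
#' decision boundary -- like the model-to-joint mapping itself -- is
#' calibrated on the labelled trials.  Both accuracies are reported.
#'
#' @param object A [mixica()] fit with `M >= 2`.
#' @param x Channels x samples matrix or `eeg_recording`.
#' @param events A `trial_events` table (onset/offset in samples, 0-based,
#'   half-open).
#' @param calibrate Use the threshold-calibrated rule when `M = 2`.
#' @return List with `trial_model` (argmax model per trial),
#'   `trial_probability` (M x trials), `trial_llr` (per-trial mean
#'   log-likelihood ratio, `M = 2` only), `mapping` (model -> joint
#'   label), `threshold`, `predicted`, `accuracy`,
#'   `accuracy_isometric`, `accuracy_isotonic`, and the uncalibrated
#'   `accuracy_argmax`.
#' @export
classify_trials_by_model <- function(object, x, events,
                                     calibrate = TRUE) {
  stopifnot(inherits(object, "mixica"))
  if (inherits(x, "eeg_recording")) x <- x$eeg
  x <- as.matrix(x)
  y <- .mixica_project(object, x)
  st <- .mixica_estep(object$models, object$priors, y, keep_scales = FALSE)
  M <- object$M
  nt <- nrow(events)
  pr <- matrix(0, M, nt)
  llr <- rep(NA_real_, nt)
  for (j in seq_len(nt)) {
    cols <- (events$onset_sample[j] + 1):events$offset_sample[j]
    lp <- rowSums(st$LA[, cols, drop = FALSE]) + log(object$priors)
    p <- exp(lp - max(lp))
    pr[, j] <- p / sum(p)
    if (M == 2)
      llr[j] <- mean(st$LA[1, cols] - st$LA[2, cols])
  }
  tm <- apply(pr, 2, which.max)
  joints <- sort(unique(as.character(events$joint)))
  ## plain rule: argmax model, best-agreement mapping over M! assignments
  perms <- .permutations(seq_len(M))
  best <- NULL
  for (pm in perms) {
    lab <- joints[pmin(pm[tm], length(joints))]
    acc <- mean(lab == events$joint)
    if (is.null(best) || acc > best$acc) best <- list(pm = pm, acc = acc)
  }
  mapping <- stats::setNames(joints[pmin(best$pm, length(joints))],
                             paste0("model", seq_len(M)))
  predicted <- unname(mapping[tm])
  acc_argmax <- mean(predicted == events$joint)
  threshold <- 0
  if (calibrate && M == 2 && length(joints) == 2) {
    ## best 1-D threshold on the per-trial mean LLR (either direction)
    o <- order(llr)
    cuts <- c(llr[o][1] - 1,
              (llr[o][-nt] + llr[o][-1]) / 2,
              llr[o][nt] + 1)
    bestc <- NULL
    for (tau in cuts) for (dir in 1:2) {
      lab <- ifelse((llr > tau) == (dir == 1), joints[1], joints[2])
      acc <- mean(lab == events$joint)
      if (is.null(bestc) || acc > bestc$acc)
        bestc <- list(tau = tau, dir = dir, acc = acc)
    }
    threshold <- bestc$tau
    predicted <- ifelse((llr > threshold) == (bestc$dir == 1),
                        joints[1], joints[2])
    mapping <- stats::setNames(
      if (bestc$dir == 1) c(joints[1], joints[2]) else
        c(joints[2], joints[1]),
      paste0("model", 1:2))
  }
  iso_m <- events$mode == "isometric"
  list(trial_model = tm,
       trial_probability = pr,
       trial_llr = llr,
       mapping = mapping,
       threshold = threshold,
       predicted = predicted,
       accuracy = mean(predicted == events$joint),
       accuracy_argmax = acc_argmax,
       accuracy_isometric = if (any(iso_m))
         mean(predicted[iso_m] == events$joint[iso_m]) else NA_real_,
       accuracy_isotonic = if (any(!iso_m))
         mean(predicted[!iso_m] == events$joint[!iso_m]) else NA_real_)
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

#' One-way ANOVA on model probabilities across subjects
#'
#' Tests whether the posterior probability of model 1 differs between the
#' knee-trial and ankle-trial data subsets across subjects (fixed-effects
#' one-way ANOVA).
#'
#' @param p_knee,p_ankle Numeric vectors: per-subject model-1 probability
#'   for the knee-data and ankle-data subsets.
#' @return List with `F`, `p`, `df`.
#' @export
anova_model_probabilities <- function(p_knee, p_ankle) {
  v <- c(p_knee, p_ankle)
  g <- factor(rep(c("knee", "ankle"), c(length(p_knee), length(p_ankle))))
  n <- length(v)
  k <- nlevels(g)
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  df1 <- k - 1
  df2 <- n - k
  if (ssw <= .Machine$double.eps * max(1, ssb)) {
    f <- if (ssb <= .Machine$double.eps) 0 else Inf
  } else f <- (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p = p, df = c(df1, df2))
}

#' Amari index between an unmixing estimate and the true mixing
#'
#' Permutation- and scale-invariant divergence of `P = W_est %*% A_true`,
#' normalized to lie in `[0, 1]`; 0 iff `P` is a scaled permutation.
#'
#' @param W_est Estimated unmixing matrix (n x n).
#' @param A_true True mixing matrix (n x n).
#' @export
amari_index <- function(W_est, A_true) {
  P <- abs(W_est %*% A_true)
  n <- nrow(P)
  stopifnot(n == ncol(P))
  r <- sum(rowSums(P) / apply(P, 1, max) - 1)
  c <- sum(colSums(P) / apply(P, 2, max) - 1)
  (r + c) / (2 * n * (n - 1))
}
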