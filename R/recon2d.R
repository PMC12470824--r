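# List-mode MLEM and the TV-regularized Split-Bregman fused iteration.
# The data term is the list-mode Poisson likelihood with unit observation
# weight per event; the regularizer is the L1 norm of the forward-
# difference image gradient, handled by one Split-Bregman inner update
# per outer iteration and applied as an additive divergence correction
# after each EM step.

#' 2D reconstruction configuration
#'
#' @param nIter number of iterations (default 30).
#' @param lambdaTV TV regularization strength (default 0.01; 0 disables).
#' @param beta Bregman parameter (default 1).
#' @param epsilonDiv denominator guard for the EM ratio (default 1e-12).
#' @param tvMode `"as_written"` (dual fields normalized by their global
#'   per-direction L2 norm) or `"shrinkage"` (componentwise soft
#'   threshold at `1/beta`).
#' @param clip clip negative intensities after the TV correction
#'   (default TRUE).
#' @return classed list of settings.
#' @export
recon2dConfig <- function(nIter = 30, lambdaTV = 0.01, beta = 1.0,
                          epsilonDiv = 1e-12,
                          tvMode = c("as_written", "shrinkage"),
                          clip = TRUE) {
  tvMode <- match.arg(tvMode)
  stopifnot(nIter >= 1, lambdaTV >= 0, beta > 0, epsilonDiv >= 0)
  structure(list(nIter = as.integer(nIter), lambdaTV = lambdaTV,
                 beta = beta, epsilonDiv = epsilonDiv, tvMode = tvMode,
                 clip = clip),
            class = "ccxfct_recon2dconfig")
}

# Forward differences with zero boundary gradients.
.forwardDiff <- function(f) {
  d <- dim(f)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  if (d[1] > 1) gx[-d[1], , ] <- f[-1, , ] - f[-d[1], , ]
  if (d[2] > 1) gy[, -d[2], ] <- f[, -1, ] - f[, -d[2], ]
  if (d[3] > 1) gz[, , -d[3]] <- f[, , -1] - f[, , -d[3]]
  list(x = gx, y = gy, z = gz)
}

# Divergence as the negative adjoint of .forwardDiff (backward
# differences with the matching boundary rows).
.divergence <- function(dx, dy, dz) {
  d <- dim(dx)
  div <- array(0, d)
  if (d[1] > 1) {
    div[1, , ] <- div[1, , ] + dx[1, , ]
    if (d[1] > 2)
      div[2:(d[1] - 1), , ] <- div[2:(d[1] - 1), , ] +
        dx[2:(d[1] - 1), , ] - dx[1:(d[1] - 2), , ]
    div[d[1], , ] <- div[d[1], , ] - dx[d[1] - 1, , ]
  }
  if (d[2] > 1) {
    div[, 1, ] <- div[, 1, ] + dy[, 1, ]
    if (d[2] > 2)
      div[, 2:(d[2] - 1), ] <- div[, 2:(d[2] - 1), ] +
        dy[, 2:(d[2] - 1), ] - dy[, 1:(d[2] - 2), ]
    div[, d[2], ] <- div[, d[2], ] - dy[, d[2] - 1, ]
  }
  if (d[3] > 1) {
    div[, , 1] <- div[, , 1] + dz[, , 1]
    if (d[3] > 2)
      div[, , 2:(d[3] - 1)] <- div[, , 2:(d[3] - 1)] +
        dz[, , 2:(d[3] - 1)] - dz[, , 1:(d[3] - 2)]
    div[, , d[3]] <- div[, , d[3]] - dz[, , d[3] - 1]
  }
  div
}

#' Total variation of a volume
#'
#' `TV(f) = sum_j sqrt((grad_x f_j)^2 + (grad_y f_j)^2 + (grad_z f_j)^2)`
#' with forward differences and zero boundary gradients.
#'
#' @param f a [ReconVolume-class] or 3D array.
#' @return nonnegative scalar; 0 iff `f` is constant.
#' @export
tvValue <- function(f) {
  if (is(f, "ReconVolume")) f <- intensities(f)
  g <- .forwardDiff(f)
  sum(sqrt(g$x^2 + g$y^2 + g$z^2))
}

#' One plain list-mode MLEM step
#'
#' `f'_j = (f_j / s_j) * sum_i a_ij / (sum_k a_ik f_k + eps)` with
#' `s_j = sum_i a_ij`; voxels with zero sensitivity stay 0.  After the
#' step the count identity `sum_j s_j f'_j = m` (number of events) holds.
#'
#' @param f intensity vector (length = voxel count) or
#'   [ReconVolume-class]; must be nonnegative with at least one positive
#'   entry.
#' @param A a [SystemMatrix-class].
#' @param epsilonDiv denominator guard.
#' @param s sensitivity vector; defaults to the column sums
#'   `sum_i a_ij` (the fused-iteration convention), but any positive
#'   sensitivity (e.g. uniform 1) can be supplied for the generic
#'   baseline update.
#' @return updated intensity in the same form as `f`.
#' @export
mlemStep <- function(f, A, epsilonDiv = 1e-12, s = sensitivity(A)) {
  asVol <- is(f, "ReconVolume")
  fv <- if (asVol) as.numeric(intensities(f)) else as.numeric(f)
  if (all(fv == 0)) stop("all-zero image: MLEM update undefined")
  proj <- .sysMatvec(A, fv)
  ratio <- 1 / (proj + epsilonDiv)
  back <- .sysTmatvec(A, ratio)
  out <- numeric(length(fv))
  pos <- s > 0
  out[pos] <- fv[pos] / s[pos] * back[pos]
  if (asVol) reconVolume(voxelGrid(f), array(out, dim = dim(intensities(f))))
  else out
}

#' List-mode log-likelihood
#'
#' `sum_i log(sum_k a_ik f_k) - sum_j s_j f_j`, the Poisson list-mode
#' objective the MLEM step ascends.
#'
#' @inheritParams mlemStep
#' @return scalar log-likelihood.
#' @export
listModeLogLik <- function(f, A, epsilonDiv = 1e-12) {
  fv <- if (is(f, "ReconVolume")) as.numeric(intensities(f))
        else as.numeric(f)
  proj <- .sysMatvec(A, fv)
  sum(log(proj + epsilonDiv)) - sum(sensitivity(A) * fv)
}

#' One Split-Bregman dual/residual update
#'
#' Given the gradient fields of the current image and the accumulated
#' Bregman residuals, updates the dual fields `d` and residuals `b` and
#' returns the divergence of `d`.  In `as_written` mode each dual field
#' is the residual-shifted gradient normalized by its global L2 norm
#' (with an epsilon guard); in `shrinkage` mode it is the componentwise
#' soft threshold at `1/beta`.
#'
#' @param grad list of gradient arrays `x`, `y`, `z` (from the current
#'   image, forward differences).
#' @param b list of residual arrays `x`, `y`, `z` (zeros at the first
#'   call).
#' @param cfg a [recon2dConfig()].
#' @return list with updated `d`, `b` and the divergence array `div`.
#' @export
bregmanUpdate <- function(grad, b, cfg = recon2dConfig()) {
  d <- list()
  for (k in c("x", "y", "z")) {
    h <- grad[[k]] + b[[k]]
    if (cfg$tvMode == "as_written") {
      nrm <- sqrt(sum(h^2))
      d[[k]] <- h / (nrm + cfg$epsilonDiv)
      if (nrm == 0) d[[k]] <- h * 0
    } else {
      d[[k]] <- sign(h) * pmax(abs(h) - 1 / cfg$beta, 0)
    }
    b[[k]] <- b[[k]] + grad[[k]] - d[[k]]
  }
  list(d = d, b = b, div = .divergence(d$x, d$y, d$z))
}

#' One fused MLEM + TV iteration
#'
#' Applies [mlemStep()] and, from the second iteration on (and when
#' `lambdaTV > 0`), adds the Split-Bregman divergence correction
#' `(lambdaTV / beta) * div` computed from the EM intermediate, clipping
#' negatives when configured.
#'
#' @param f current intensity ([ReconVolume-class]).
#' @param state list with Bregman residuals `b` (use
#'   `initBregmanState(grid)` at the start).
#' @param A a [SystemMatrix-class].
#' @param cfg a [recon2dConfig()].
#' @param iter 0-based iteration counter; the TV correction is applied
#'   for `iter >= 1`.
#' @return list with updated `f` and `state`.
#' @export
fusedStep <- function(f, state, A, cfg = recon2dConfig(), iter = 1L) {
  fm <- mlemStep(f, A, cfg$epsilonDiv)
  if (cfg$lambdaTV > 0 && iter >= 1L) {
    g <- .forwardDiff(intensities(fm))
    up <- bregmanUpdate(g, state$b, cfg)
    state$b <- up$b
    newArr <- intensities(fm) + (cfg$lambdaTV / cfg$beta) * up$div
    if (isTRUE(cfg$clip)) newArr[newArr < 0] <- 0
    fm <- reconVolume(voxelGrid(fm), newArr)
  }
  list(f = fm, state = state)
}

#' Fresh Bregman state (zero residuals)
#'
#' @param grid a [VoxelGrid-class].
#' @return list with residual arrays `b$x`, `b$y`, `b$z`.
#' @export
initBregmanState <- function(grid) {
  z <- array(0, dim = as.integer(grid@dims))
  list(b = list(x = z, y = z, z = z))
}

#' TV-regularized list-mode MLEM reconstruction
#'
#' Assembles the system matrix once, initializes the image to 1 on all
#' voxels with positive sensitivity, and runs `nIter` fused iterations,
#' keeping every iterate and logging per-iteration TV and log-likelihood.
#' With `lambdaTV = 0` this is exactly the baseline LM-MLEM trajectory.
#'
#' @param events a non-empty [ComptonEvents-class].
#' @param grid a [VoxelGrid-class].
#' @param muVol optional attenuation map ([ReconVolume-class], 1/mm).
#' @param cfg a [recon2dConfig()].
#' @param sigmaCone cone kernel width, radians.
#' @param A optional pre-assembled [SystemMatrix-class] (overrides
#'   `events`/`grid`/`muVol`).
#' @return list of class `ccxfct_recon2d` with elements `volumes` (list
#'   of [ReconVolume-class], one per iteration), `log` (data.frame:
#'   iter, tv, logLik) and `grid`.
#' @export
reconstruct2d <- function(events, grid, muVol = NULL,
                          cfg = recon2dConfig(), sigmaCone = 2 * .DEG,
                          A = NULL) {
  if (is.null(A)) {
    if (nEvents(events) == 0L) stop("no events to reconstruct")
    A <- assembleMatrix(events, grid, muVol, sigmaCone)
  }
  grid <- voxelGrid(A)
  s <- sensitivity(A)
  f <- reconVolume(grid, array(as.numeric(s > 0),
                               dim = as.integer(grid@dims)))
  state <- initBregmanState(grid)
  volumes <- vector("list", cfg$nIter)
  logTab <- data.frame(iter = seq_len(cfg$nIter), tv = NA_real_,
                       logLik = NA_real_)
  for (it in seq_len(cfg$nIter)) {
    res <- fusedStep(f, state, A, cfg, iter = it - 1L)
    f <- res$f; state <- res$state
    volumes[[it]] <- f
    logTab$tv[it] <- tvValue(f)
    logTab$logLik[it] <- listModeLogLik(f, A, cfg$epsilonDiv)
  }
  structure(list(volumes = volumes, log = logTab, grid = grid),
            class = "ccxfct_recon2d")
}
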