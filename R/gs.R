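#' Gerchberg-Saxton iterative phase retrieval
#'
#' Classic alternating-projection reconstruction for in-line holograms:
#' the detector field (initialized as `sqrt(H)` with zero phase) is
#' back-propagated to the object plane, the object-domain constraints are
#' applied (transmission magnitude capped at 1, i.e. no gain, and
#' non-positive phase, matching refractive-index-decrement materials), the
#' constrained transmission is propagated forward, and the detector
#' amplitude is replaced by the measured `sqrt(H)` while keeping the
#' simulated phase.  The iterate with the smallest detector-amplitude
#' residual is returned.
#'
#' @param H A [hologram()] (nonnegative intensities).
#' @param grid A [wavefield_grid()].
#' @param distance Object-detector distance in metres (> 0).
#' @param n_iter Maximum number of iterations (default 500).
#' @param tol Early exit when the detector residual changes by less than
#'   this amount between iterations (default 1e-8).
#' @return A [reconstruction_result()] with the phase map `arg(t)`, the
#'   absorbance map `-log|t|`, and the residual history in `$details`.
#' @export
gs_reconstruct <- function(H, grid, distance, n_iter = 500L, tol = 1e-8) {
  I <- hologram_intensity(H)
  if (any(I < 0)) stop("hologram intensities must be nonnegative", call. = FALSE)
  stopifnot(inherits(grid, "wavefield_grid"), distance > 0, n_iter >= 1)
  if (nrow(I) != grid$L || ncol(I) != grid$M) {
    stop("hologram shape does not match grid", call. = FALSE)
  }
  amp <- sqrt(I)
  # Kernels referenced to the plane-wave carrier (DC term), so the unit
  # background keeps zero phase and the object constraints act on the
  # transmission relative to the incident beam.
  Kb <- asm_transfer(grid, -distance)
  Kf <- asm_transfer(grid, distance)
  Kb <- Kb / Kb[1, 1]
  Kf <- Kf / Kf[1, 1]
  det_field <- amp + 0i
  best <- list(res = Inf, t = NULL, iter = 0L)
  res_hist <- numeric(n_iter)
  prev_res <- Inf
  for (it in seq_len(n_iter)) {
    obj <- prop_apply(det_field, Kb)
    tmag <- pmin(Mod(obj), 1)
    tphase <- pmin(Arg(obj), 0)
    t_obj <- tmag * exp(1i * tphase)
    det_sim <- prop_apply(t_obj, Kf)
    res <- sqrt(mean((Mod(det_sim) - amp)^2))
    res_hist[it] <- res
    if (res < best$res) best <- list(res = res, t = t_obj, iter = it)
    if (abs(prev_res - res) < tol) { res_hist <- res_hist[seq_len(it)]; break }
    prev_res <- res
    det_field <- amp * exp(1i * Arg(det_sim))
  }
  if (best$iter < length(res_hist) && best$res < res_hist[length(res_hist)]) {
    warning("GS residual was not monotone; returning the best iterate",
            call. = FALSE)
  }
  t_best <- best$t
  reconstruction_result(
    phase = Arg(t_best),
    absorbance = -log(pmax(Mod(t_best), .Machine$double.eps)),
    method = "gerchberg_saxton",
    details = list(residual = res_hist, best_iter = best$iter,
                   n_iter = length(res_hist), distance = distance)
  )
}
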