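## Mean-squared displacement with multiple time origins, diffusive-regime
## validation via the log-log slope beta, Einstein-relation diffusion
## coefficients, and the percent relative-error metric for simulated vs
## experimental values.

#' Mean-squared displacement
#'
#' Multiple-time-origin average of |r(t0 + tau) - r(t0)|^2 over origins
#' and entities.  Uses unwrapped coordinates when the trajectory carries
#' them (`traj$unwrapped`, as the Brownian generator provides); otherwise
#' unwraps by accumulating minimum-image steps between consecutive
#' frames, which is valid as long as no entity moves more than half a box
#' edge per frame.
#'
#' @param traj a [trajectory()] with at least 10 frames.
#' @param sel atom indices (1-based); default all atoms.
#' @param mode `"per_particle"` (each selected atom is an entity),
#'   `"molecule_com"` (one entity per molecule in the selection, COM of
#'   its atoms), or `"com"` (a single entity: the COM of the whole
#'   selection, made PBC-whole per frame) — the micelle convention.
#' @param max_lag_fraction largest lag as a fraction of the trajectory
#'   length (default 0.5).
#' @param origin_stride take every `stride`-th frame as a time origin
#'   (default 1: every frame).
#' @return an object of class `"msd_result"`: `lag` (ps), `msd` (nm^2),
#'   `n_entities`, `mode`.  MSD(0) = 0 is implicit and not stored.
#' @export
msd <- function(traj, sel = seq_len(n_atoms(traj)),
                mode = c("per_particle", "molecule_com", "com"),
                max_lag_fraction = 0.5, origin_stride = 1L) {
  mode <- match.arg(mode)
  nf <- n_frames(traj)
  if (nf < 10) stop("MSD needs at least 10 frames")
  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("MSD requires evenly spaced frames")
  unwrapped <- traj$unwrapped
  if (is.null(unwrapped)) unwrapped <- unwrap_frames(traj)
  masses <- traj$topology$mass
  ent <- switch(mode,
    per_particle = lapply(unwrapped, function(m) m[sel, , drop = FALSE]),
    molecule_com = {
      mol <- traj$topology$residue_id[sel]
      lapply(unwrapped, function(m) {
        x <- m[sel, , drop = FALSE] * masses[sel]
        sums <- rowsum(x, mol)
        sums / as.numeric(rowsum(matrix(masses[sel]), mol))
      })
    },
    com = lapply(unwrapped, function(m) {
      x <- m[sel, , drop = FALSE]
      matrix(colSums(x * masses[sel]) / sum(masses[sel]), 1, 3)
    }))
  ne <- nrow(ent[[1]])
  big <- t(vapply(ent, function(m) as.numeric(t(m)), numeric(3 * ne)))
  max_lag <- max(5L, floor((nf - 1) * max_lag_fraction))
  out <- .msd_kernel(big, as.integer(max_lag), as.integer(origin_stride))
  structure(list(lag = dt[1] * seq_len(max_lag), msd = out,
                 n_entities = ne, mode = mode), class = "msd_result")
}

# Unwrap wrapped frames by accumulated minimum-image steps.
unwrap_frames <- function(traj) {
  nf <- n_frames(traj)
  out <- vector("list", nf)
  out[[1]] <- traj$frames[[1]]$coords
  if (nf == 1) return(out)
  for (i in 2:nf) {
    fr <- traj$frames[[i]]
    if (is.null(fr$box))
      stop("cannot unwrap a frame without a box")
    step <- minimum_image(traj$frames[[i - 1]]$coords, fr$coords, fr$box)
    out[[i]] <- out[[i - 1]] + rbind_coords(step)
  }
  out
}

#' Log-log slope beta(tau) and the diffusive window
#'
#' beta(tau) = d ln MSD / d ln tau via centred finite differences
#' (one-sided at the ends).  The diffusive window is the longest
#' contiguous run of lags with |beta - 1| <= `tol`; the series is flagged
#' non-diffusive when that window spans less than `min_window_frac` of
#' the available lags.
#'
#' @param msd_result an `msd_result` with >= 5 positive-lag points.
#' @param tol tolerance on |beta - 1| (default 0.1).
#' @param min_window_frac minimum window span as a fraction of lags
#'   (default 0.2).
#' @return list with `beta` (per lag), `window` (integer index range into
#'   the lag vector, or NULL), `diffusive` (flag).
#' @export
beta_exponent <- function(msd_result, tol = 0.1, min_window_frac = 0.2) {
  m <- msd_result$msd; tau <- msd_result$lag
  n <- length(m)
  if (n < 5) stop("need at least 5 positive-lag MSD points")
  if (any(m <= 0))
    stop("MSD contains non-positive values at positive lag; ",
         "beta is undefined")
  lm_ <- log(m); lt <- log(tau)
  beta <- numeric(n)
  beta[1] <- (lm_[2] - lm_[1]) / (lt[2] - lt[1])
  beta[n] <- (lm_[n] - lm_[n - 1]) / (lt[n] - lt[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    beta[i] <- (lm_[i + 1] - lm_[i - 1]) / (lt[i + 1] - lt[i - 1])
  }
  ok <- abs(beta - 1) <= tol
  runs <- rle(ok)
  window <- NULL
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    window <- c(starts[best], ends[best])
  }
  diffusive <- !is.null(window) &&
    (window[2] - window[1] + 1L) >= min_window_frac * n
  list(beta = beta, window = window, diffusive = diffusive)
}

#' Einstein-relation diffusion coefficient
#'
#' Least-squares slope of MSD versus lag time over the diffusive window,
#' D = slope / 6 (three dimensions).  An additive constant in the MSD is
#' absorbed by the intercept.
#'
#' @param msd_result an `msd_result`.
#' @param window integer `c(from, to)` index range into the lag vector;
#'   defaults to the diffusive window found by [beta_exponent()].
#' @return list with `d` (nm^2/ps), `d_si` (units of 1e-11 m^2/s),
#'   `se` (fit standard error on D, nm^2/ps), `window`, `diffusive`.
#' @export
diffusion_coefficient <- function(msd_result, window = NULL) {
  diffusive <- NA
  if (is.null(window)) {
    bw <- beta_exponent(msd_result)
    if (is.null(bw$window))
      stop("no diffusive window found; supply one explicitly")
    window <- bw$window
    diffusive <- bw$diffusive
  }
  idx <- seq.int(window[1], window[2])
  if (length(idx) < 3) stop("diffusive window shorter than 3 points")
  fit <- stats::lm(msd_result$msd[idx] ~ msd_result$lag[idx])
  # exact analytic series fit perfectly; the zero-residual warning from
  # summary.lm is expected there, not a problem
  co <- suppressWarnings(summary(fit)$coefficients)
  d <- co[2, 1] / 6
  list(d = d, d_si = d * 1e5, se = co[2, 2] / 6, window = window,
       diffusive = diffusive)
}

#' Percent relative error of a simulated value
#'
#' |x_exp - x_sim| / x_exp * 100.
#'
#' @param x_exp experimental (reference) value, non-zero.
#' @param x_sim simulated value.
#' @return percent error.
#' @export
relative_error <- function(x_exp, x_sim) {
  if (any(x_exp == 0)) stop("reference value must be non-zero")
  abs(x_exp - x_sim) / abs(x_exp) * 100
}

#' Write a transport report table
#'
#' @param entries named list; each element a list with `msd_result` and
#'   optionally a precomputed `d` (as from [diffusion_coefficient()]).
#' @param path output TSV path.
#' @return invisibly, the data frame written.
#' @export
write_transport_report <- function(entries, path) {
  df <- do.call(rbind, lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    bw <- beta_exponent(e$msd_result)
    win <- bw$window
    if (is.null(win) || win[2] - win[1] < 2) {
      # no usable diffusive window: report the full-range fit, flagged
      win <- c(1L, length(e$msd_result$lag))
      bw$diffusive <- FALSE
      bw$window <- win
    }
    dd <- e$d %||% diffusion_coefficient(e$msd_result, window = win)
    data.frame(species = nm,
               D_1e11_m2s = signif(dd$d_si, 4),
               fit_se_1e11_m2s = signif(dd$se * 1e5, 3),
               window_from_ps = e$msd_result$lag[bw$window[1]],
               window_to_ps = e$msd_result$lag[bw$window[2]],
               diffusive = bw$diffusive,
               stringsAsFactors = FALSE)
  }))
  write_tsv_report(df, path,
                   "Einstein-relation diffusion coefficients (D in 1e-11 m^2/s)")
  invisible(df)
}
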