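#' Tissue and sequence parameters of the SPGR steady-state signal model
#'
#' Bundles the constants of the spoiled-gradient-echo (SPGR) steady-state
#' signal equation for one voxel (or one homogeneous compartment): the
#' equilibrium magnetization, the net complex receive weight after channel
#' combination, the transmit phase, the sequence timings, the relaxation
#' times, and the reference flip angle reached at unit transmit sensitivity
#' and unit RF drive.
#'
#' @param TR Repetition time in ms (> 0).
#' @param T1 Longitudinal relaxation time in ms (> 0).
#' @param theta_ref Reference flip angle in radians (> 0): the flip angle
#'   produced when the transmit sensitivity \eqn{f} and the RF drive \eqn{d}
#'   are both 1.
#' @param TE Echo time in ms (>= 0). Default 0.
#' @param T2star Apparent transverse relaxation time in ms (> 0). Default
#'   `Inf` (no T2* weighting).
#' @param M0 Equilibrium magnetization, arbitrary units (> 0). Default 1.
#' @param R Net complex receive weight (unitless). Default 1.
#' @param phi Transmit phase in radians. Default 0.
#'
#' @return An object of class `spgr_params`.
#' @seealso [spgr_signal()], [saturation_error()], [min_drive()]
#' @export
#' @examples
#' p <- spgr_params(TR = 6, T1 = 451, theta_ref = 273 * pi / 180, TE = 4,
#'                  T2star = 100)
#' spgr_signal(p, f = 0.5, d = 0.1)
spgr_params <- function(TR, T1, theta_ref, TE = 0, T2star = Inf,
                        M0 = 1, R = 1 + 0i, phi = 0) {
  stopifnot(is.numeric(TR), length(TR) == 1L, TR > 0,
            is.numeric(T1), length(T1) == 1L, T1 > 0,
            is.numeric(TE), length(TE) == 1L, TE >= 0,
            is.numeric(T2star), length(T2star) == 1L, T2star > 0,
            is.numeric(M0), length(M0) == 1L, M0 > 0,
            length(R) == 1L,
            is.numeric(phi), length(phi) == 1L,
            is.numeric(theta_ref), length(theta_ref) == 1L, theta_ref > 0)
  if (TE >= 50 * T2star)
    stop("TE is implausibly long relative to T2star")
  structure(list(M0 = M0, R = as.complex(R), phi = phi, TR = TR, TE = TE,
                 T1 = T1, T2star = T2star, theta_ref = theta_ref),
            class = "spgr_params")
}

#' @export
print.spgr_params <- function(x, ...) {
  cat("SPGR model parameters\n")
  cat(sprintf("  TR = %g ms, TE = %g ms, T1 = %g ms, T2* = %g ms\n",
              x$TR, x$TE, x$T1, x$T2star))
  cat(sprintf("  theta_ref = %g rad (%.1f deg), M0 = %g, |R| = %g, phi = %g rad\n",
              x$theta_ref, x$theta_ref * 180 / pi, x$M0, Mod(x$R), x$phi))
  invisible(x)
}

# constant prefactor M0 * R * exp(-TE/T2*) * exp(i*phi); rho = this * theta_ref
spgr_prefactor <- function(params) {
  params$M0 * params$R * exp(-params$TE / params$T2star) * exp(1i * params$phi)
}

#' SPGR steady-state signal
#'
#' Noise-free steady-state signal of a spoiled gradient echo sequence at flip
#' angle \eqn{\theta = f d \theta_{ref}}:
#' \deqn{S = M_0 R (1 - E_1) e^{-TE/T_2^*} e^{i\phi}
#'           \frac{\sin\theta}{1 - E_1\cos\theta}, \quad E_1 = e^{-TR/T_1}.}
#' Noise is added by the phantom and Monte Carlo modules, not here.
#'
#' @param params An [spgr_params()] object.
#' @param f Transmit sensitivity (unitless, >= 0); may be a vector.
#' @param d RF drive scale in (0, 1]; may be a vector (recycled against `f`).
#' @return Complex signal value(s).
#' @export
spgr_signal <- function(params, f, d) {
  stopifnot(inherits(params, "spgr_params"),
            is.numeric(f), all(f >= 0),
            is.numeric(d), all(d > 0), all(d <= 1))
  E1 <- exp(-params$TR / params$T1)
  theta <- f * d * params$theta_ref
  spgr_prefactor(params) * (1 - E1) * sin(theta) / (1 - E1 * cos(theta))
}

#' Low-flip-angle (linear) SPGR signal
#'
#' The tangent of the SPGR signal equation at zero flip angle,
#' \eqn{S_{lin} = \rho f d} with
#' \eqn{\rho = M_0 R e^{-TE/T_2^*} e^{i\phi} \theta_{ref}}: the signal that
#' would be measured if the sequence were perfectly linear in flip angle
#' (no saturation). The normalized signal \eqn{S_j / d_j} of an unsaturated
#' measurement estimates \eqn{\rho f}.
#'
#' @inheritParams spgr_signal
#' @return Complex signal value(s).
#' @export
linear_signal <- function(params, f, d) {
  stopifnot(inherits(params, "spgr_params"),
            is.numeric(f), all(f >= 0),
            is.numeric(d), all(d > 0), all(d <= 1))
  spgr_prefactor(params) * params$theta_ref * f * d
}

#' Relative saturation error of the low-flip-angle approximation
#'
#' Fractional amount by which the true SPGR signal magnitude falls below the
#' linear (tangent-at-zero) approximation at flip angle `theta`:
#' \deqn{1 - \frac{|S(\theta)|}{|S_{lin}(\theta)|}
#'     = 1 - \frac{\sin\theta}{1 - E_1\cos\theta}\cdot\frac{1 - E_1}{\theta}.}
#' It is 0 at \eqn{\theta = 0}, grows like
#' \eqn{\theta^2 (1/6 + E_1 / (2(1 - E_1)))} for small angles, and depends on
#' the sequence only through \eqn{TR/T_1}.
#'
#' @param params An [spgr_params()] object (only `TR` and `T1` matter).
#' @param theta Flip angle(s) in radians, in `[0, pi)`.
#' @return Relative error(s) in `[0, 1]` on `[0, pi/2]`.
#' @export
saturation_error <- function(params, theta) {
  stopifnot(inherits(params, "spgr_params"), is.numeric(theta),
            all(theta >= 0))
  if (any(theta >= pi))
    stop("saturation_error is defined for flip angles below pi radians")
  E1 <- exp(-params$TR / params$T1)
  out <- 1 - (sin(theta) / (1 - E1 * cos(theta))) * (1 - E1) / theta
  out[theta == 0] <- 0
  out
}

#' Minimum RF drive satisfying a linearity tolerance
#'
#' Finds the largest drive scale `d` such that the voxel with the highest
#' expected transmit sensitivity `f_max` still produces a signal within
#' `tol` of the linear approximation, i.e.
#' `saturation_error(f_max * d * theta_ref) <= tol`. This is the rule used to
#' set the lowest drive of an acquisition scheme so that at least the first
#' measurement is unsaturated everywhere.
#'
#' Solved by bisection on `d` in `[1e-6, 1]`; the saturation error is
#' monotone in `d` over the relevant range (flip angles at or beyond pi
#' radians are treated as fully saturated).
#'
#' @param params An [spgr_params()] object.
#' @param f_max Maximum expected transmit sensitivity (> 0).
#' @param tol Linearity tolerance in (0, 0.5), e.g. 0.01 for 1 % accuracy.
#' @return A drive scale in (0, 1]. If even full drive meets the tolerance,
#'   returns 1 with a message (attribute `capped = TRUE`).
#' @export
#' @examples
#' p <- spgr_params(TR = 1, T1 = 100, theta_ref = 273 * pi / 180)
#' d <- min_drive(p, f_max = 1, tol = 0.01)  # approx 0.003
min_drive <- function(params, f_max, tol = 0.01) {
  stopifnot(inherits(params, "spgr_params"),
            is.numeric(f_max), length(f_max) == 1L, f_max > 0,
            is.numeric(tol), length(tol) == 1L, tol > 0, tol < 0.5)
  err_at <- function(d) {
    theta <- f_max * d * params$theta_ref
    if (theta >= pi) 1 else saturation_error(params, theta)
  }
  if (err_at(1) <= tol) {
    message("full drive already linear to the requested tolerance; ",
            "returning d = 1")
    return(structure(1, capped = TRUE))
  }
  lo <- 1e-6
  if (err_at(lo) > tol)
    stop("linearity tolerance unattainable even at drive 1e-6; ",
         "check f_max and theta_ref")
  hi <- 1
  # bisection; err_at is monotone nondecreasing in d
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (err_at(mid) <= tol) lo <- mid else hi <- mid
  }
  lo
}

#' Build an RF drive sampling scheme
#'
#' Constructs the ordered set of N drive scales between `d_min` and 1.
#' Linear sampling spaces them equally; logarithmic sampling spaces them
#' geometrically, \eqn{d_j = d_{min}^{(N-j)/(N-1)}}, concentrating drives at
#' the low end of the range where the transmit-sensitivity dynamic range
#' needs them most.
#'
#' @param d_min Lowest drive scale, in (0, 1).
#' @param N Number of drives (>= 2).
#' @param kind `"linear"` or `"logarithmic"`.
#' @return A `drive_scheme` object: a strictly ascending numeric vector of
#'   drives ending at 1, with attribute `kind`.
#' @export
#' @examples
#' make_drive_scheme(0.01, 4, "logarithmic")  # 0.01 0.0464 0.2154 1
make_drive_scheme <- function(d_min, N, kind = c("logarithmic", "linear")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(d_min), length(d_min) == 1L, d_min > 0, d_min < 1,
            is.numeric(N), length(N) == 1L)
  if (N < 2) stop("a drive scheme needs at least 2 drives")
  j <- seq_len(N)
  drives <- switch(kind,
    linear      = seq(d_min, 1, length.out = N),
    logarithmic = d_min^((N - j) / (N - 1)))
  drives[N] <- 1
  drive_scheme(drives, kind = kind)
}

#' Construct a drive scheme from explicit drive values
#'
#' @param drives Strictly ascending drive scales in (0, 1].
#' @param kind Label for how the drives were generated; `"explicit"` when
#'   given by hand.
#' @return A `drive_scheme` object.
#' @export
drive_scheme <- function(drives, kind = "explicit") {
  stopifnot(is.numeric(drives), length(drives) >= 1L,
            all(drives > 0), all(drives <= 1))
  if (is.unsorted(drives, strictly = TRUE))
    stop("drives must be strictly ascending")
  structure(as.numeric(drives), kind = kind, class = "drive_scheme")
}

#' @export
print.drive_scheme <- function(x, ...) {
  cat(sprintf("RF drive scheme (%s, N = %d):\n", attr(x, "kind"), length(x)))
  cat(" ", paste(signif(unclass(x), 4), collapse = "  "), "\n")
  invisible(x)
}
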