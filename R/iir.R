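# IIR design in zero-pole-gain form, applied as cascaded second-order
# sections (biquads). Transfer-function (b, a) coefficients of high-order
# designs with band edges far below Nyquist (e.g. an order-6 Chebyshev II
# band-pass with a 0.5 Hz lower edge at fs = 1000 Hz) are numerically
# unstable in double precision, so poles and zeros are never expanded into
# a single polynomial here: analytic analog prototypes are frequency
# transformed (signal::sftrans), discretised (signal::bilinear) and grouped
# into biquads.

butter_prototype <- function(n) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # force exact conjugate symmetry
  p[abs(Im(p)) < 1e-12] <- Re(p[abs(Im(p)) < 1e-12])
  list(z = complex(0), p = p, g = 1)
}

cheby2_prototype <- function(n, rs) {
  de <- 1 / sqrt(10^(rs / 10) - 1)
  mu <- asinh(1 / de) / n
  k <- seq_len(n)
  th <- pi * (2 * k - 1) / (2 * n)
  p <- 1 / (-sinh(mu) * sin(th) + 1i * cosh(mu) * cos(th))
  # odd n: the middle zero (theta = pi/2) sits at infinity and drops out
  z <- 1i / cos(th[2 * k - 1 != n])
  g <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, g = g)
}

# Digital IIR design.
# kind: "low", "high", "pass" or "stop"; w: edge(s) as a fraction of the
# Nyquist frequency; type: "butter" or "cheby2" (rs = stopband ripple, dB).
design_iir <- function(n, w, kind = c("low", "high", "pass", "stop"),
                       type = c("butter", "cheby2"), rs = 40) {
  kind <- match.arg(kind)
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) {
    stop("band edges must lie strictly inside (0, Nyquist)")
  }
  proto <- switch(type, butter = butter_prototype(n),
                  cheby2 = cheby2_prototype(n, rs))
  W <- tan(pi * w / 2)                   # bilinear prewarp (T = 2)
  zpg <- signal::Zpg(zero = proto$z, pole = proto$p, gain = proto$g)
  zpg <- signal::sftrans(zpg, W = W, stop = kind %in% c("high", "stop"))
  zpg <- signal::bilinear(zpg, T = 2)
  zpk_to_sos(zpg$zero, zpg$pole, Re(zpg$gain))
}

# Group conjugate root pairs into biquad sections; returns a matrix with
# columns b0 b1 b2 a1 a2 (a0 = 1), overall gain folded into section 1.
zpk_to_sos <- function(z, p, g, tol = 1e-8) {
  quads <- function(r) {
    cpx <- r[Im(r) > tol]
    out <- lapply(cpx, function(ri) c(1, -2 * Re(ri), Mod(ri)^2))
    re <- sort(Re(r[abs(Im(r)) <= tol]))
    while (length(re) >= 2) {
      out <- c(out, list(c(1, -(re[1] + re[2]), re[1] * re[2])))
      re <- re[-(1:2)]
    }
    if (length(re) == 1) out <- c(out, list(c(1, -re[1], 0)))
    out
  }
  zq <- quads(z)
  pq <- quads(p)
  while (length(zq) < length(pq)) zq <- c(zq, list(c(1, 0, 0)))
  if (length(zq) > length(pq)) stop("more zeros than poles in design")
  # pair each pole section (nearest unit circle first) with the zero
  # section whose roots are closest in angle
  pole_mag <- vapply(pq, function(q) {
    max(Mod(polyroot(rev(q))))
  }, numeric(1))
  ord <- order(pole_mag, decreasing = TRUE)
  pq <- pq[ord]
  sec_angle <- function(q) {
    r <- polyroot(rev(q))
    mean(abs(Arg(r)))
  }
  za <- vapply(zq, sec_angle, numeric(1))
  sos <- matrix(0, nrow = length(pq), ncol = 5)
  for (i in seq_along(pq)) {
    pa <- sec_angle(pq[[i]])
    j <- which.min(abs(za - pa))
    sos[i, ] <- c(zq[[j]], pq[[i]][2:3])
    zq <- zq[-j]; za <- za[-j]
  }
  sos[1, 1:3] <- sos[1, 1:3] * g
  sos
}

# Causal cascade: direct-form-I biquads with zero initial conditions; the
# recursive half runs in C via stats::filter.
sos_filter <- function(sos, x) {
  y <- x
  n <- length(x)
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:5]
    u <- b[1] * y
    if (n > 1) u[2:n] <- u[2:n] + b[2] * y[1:(n - 1)]
    if (n > 2) u[3:n] <- u[3:n] + b[3] * y[1:(n - 2)]
    y <- if (all(a == 0)) u else {
      as.numeric(stats::filter(u, -a, method = "recursive"))
    }
  }
  y
}

# Zero-phase (forward-backward) application with odd-reflection padding so
# edge transients decay inside the padding, not the signal.
sos_filtfilt <- function(sos, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 6000L)
  if (pad < 1) stop("segment too short for zero-phase filtering")
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sos_filter(sos, ext)
  y <- rev(sos_filter(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_freq_response <- function(sos, f, fs) {
  w <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * w + sos[i, 3] * w^2
    den <- 1 + sos[i, 4] * w + sos[i, 5] * w^2
    h <- h * num / den
  }
  h
}
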