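# Independent oracles, written naively (explicit loops, direct formulas)
# so they share no code path with the package implementations.

# Exhaustive-scan Renyi-entropy threshold: for every candidate grey level
# compute the two-class Renyi entropies directly at orders 1/2, 1, 2, take
# each argmax (lowest level on ties), and combine with the published
# three-estimate rule.
oracle_renyi_threshold <- function(h) {
  p <- h / sum(h)
  L <- length(p)
  class_entropy <- function(pcls, alpha) {
    P <- sum(pcls)
    q <- pcls[pcls > 0] / P
    if (alpha == 1) -sum(q * log(q))
    else (1 / (1 - alpha)) * log(sum(q^alpha))
  }
  best_t <- function(alpha) {
    bt <- NA_integer_
    bv <- -Inf
    for (t in seq_len(L - 1L)) {
      P1 <- sum(p[1:t])
      if (P1 <= 0 || P1 >= 1) next
      v <- class_entropy(p[1:t], alpha) +
        class_entropy(p[(t + 1L):L], alpha)
      if (v > bv) {
        bv <- v
        bt <- t
      }
    }
    bt
  }
  ts <- sort(c(best_t(0.5), best_t(1), best_t(2)))
  t1 <- ts[1L]; t2 <- ts[2L]; t3 <- ts[3L]
  b <- if (abs(t1 - t2) <= 5 && abs(t2 - t3) <= 5) c(1, 2, 1)
    else if (abs(t1 - t2) <= 5 && abs(t2 - t3) > 5) c(0, 1, 3)
    else if (abs(t1 - t2) > 5 && abs(t2 - t3) <= 5) c(3, 1, 0)
    else c(1, 2, 1)
  P1 <- function(t) sum(p[1:t])
  om <- P1(t3) - P1(t1)
  floor((t1 - 1) * (P1(t1) + 0.25 * om * b[1L]) +
          0.25 * (t2 - 1) * om * b[2L] +
          (t3 - 1) * (1 - P1(t3) + 0.25 * om * b[3L]))
}

# Random plausible image histograms: mixtures of two discretised gaussian
# modes plus uniform clutter, always >= 2 occupied bins.
random_histogram <- function(L = 256L) {
  repeat {
    n1 <- sample(50:5000, 1)
    n2 <- sample(10:2000, 1)
    m1 <- runif(1, 5, 100)
    m2 <- runif(1, 110, 250)
    s1 <- runif(1, 1, 25)
    s2 <- runif(1, 1, 40)
    lv <- c(pmin(pmax(round(rnorm(n1, m1, s1)), 0), L - 1),
            pmin(pmax(round(rnorm(n2, m2, s2)), 0), L - 1),
            sample.int(L, sample(0:30, 1), replace = TRUE) - 1L)
    h <- tabulate(lv + 1L, nbins = L)
    if (sum(h > 0) >= 2L) return(h)
  }
}

# Bisection oracle for the implicit aerodynamic-diameter equation
# d_ae^2 Cc(d_ae) rho0 = d_ve^2 Cc(d_ve) rho_p / chi.
oracle_aerodynamic_bisect <- function(dPa, cfg, tol = 1e-10) {
  cc <- function(d) {
    kn <- 2 * cfg@meanFreePath / d
    1 + kn * (1.142 + 0.558 * exp(-0.999 / kn))
  }
  dVe <- (6 * cfg@volumeShapeFactor / pi)^(1 / 3) * dPa
  rhs <- dVe^2 * cc(dVe) * cfg@particleDensity /
    (cfg@dynamicShapeFactor * cfg@referenceDensity)
  f <- function(x) x^2 * cc(x) - rhs
  lo <- dPa * 1e-3
  hi <- dPa * 1e3
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) / mid < tol) break
  }
  (lo + hi) / 2
}

# Small all-default config shared across tests
test_config <- function(...) samplerConfig(...)

# A tiny scenario that renders in well under a second
tiny_scenario <- function(trueConcentration = 0.2, seed = 1L, ...) {
  truthScenario(trueConcentration, depositionArea = 0.15, nTiles = 4L,
                contaminationRate = 0, seed = seed, ...)
}

# Draw a single ellipse of known pixel area on a quiet background
single_particle_tile <- function(area_px, S = 200L, grey = 210L, bg = 30L,
                                 pixelSide = 0.64, aspect = 1.5,
                                 theta = 0.3) {
  a <- sqrt(area_px * aspect / pi)
  b <- a / aspect
  m <- matrix(bg, S, S)
  x0 <- S / 2 + 0.37
  y0 <- S / 2 - 0.21
  for (i in 1:S) for (j in 1:S) {
    dx <- j - 0.5 - x0
    dy <- i - 0.5 - y0
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) m[i, j] <- grey
  }
  SemTile(m, pixelSide = pixelSide, tileIndex = 1L, stubId = "single")
}
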