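# Independent straight-line transcription of the published Canadian FWI
# equation chain (scalar, one branch at a time, no vectorization).  This
# is the reference oracle the package implementation is checked against;
# it is deliberately written without reference to the package code.

oracle_ffmc <- function(ffmc0, temp, rh, wind, rain) {
  mo <- 147.27723 * (101 - ffmc0) / (59.5 + ffmc0)
  if (rain > 0.5) {
    rf <- rain - 0.5
    if (mo > 150) {
      mo <- mo + 42.5 * rf * exp(-100 / (251 - mo)) * (1 - exp(-6.93 / rf)) +
        0.0015 * (mo - 150)^2 * sqrt(rf)
    } else {
      mo <- mo + 42.5 * rf * exp(-100 / (251 - mo)) * (1 - exp(-6.93 / rf))
    }
    if (mo > 250) mo <- 250
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  if (mo > ed) {
    ko <- 0.424 * (1 - (rh / 100)^1.7) +
      0.0694 * sqrt(wind) * (1 - (rh / 100)^8)
    kd <- ko * 0.581 * exp(0.0365 * temp)
    m <- ed + (mo - ed) * 10^(-kd)
  } else {
    ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
      0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
    if (mo < ew) {
      k1 <- 0.424 * (1 - ((100 - rh) / 100)^1.7) +
        0.0694 * sqrt(wind) * (1 - ((100 - rh) / 100)^8)
      kw <- k1 * 0.581 * exp(0.0365 * temp)
      m <- ew - (ew - mo) * 10^(-kw)
    } else {
      m <- mo
    }
  }
  f <- 59.5 * (250 - m) / (147.27723 + m)
  if (f > 101) f <- 101
  if (f < 0) f <- 0
  f
}

oracle_dmc <- function(dmc0, temp, rh, rain, month) {
  el <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
  p0 <- dmc0
  if (rain > 1.5) {
    re <- 0.92 * rain - 1.27
    mo <- 20 + exp(5.6348 - p0 / 43.43)
    if (p0 <= 33) {
      b <- 100 / (0.5 + 0.3 * p0)
    } else if (p0 <= 65) {
      b <- 14 - 1.3 * log(p0)
    } else {
      b <- 6.2 * log(p0) - 17.2
    }
    mr <- mo + 1000 * re / (48.77 + b * re)
    p0 <- 43.43 * (5.6348 - log(mr - 20))
    if (p0 < 0) p0 <- 0
  }
  tt <- temp
  if (tt < -1.1) tt <- -1.1
  k <- 1.894 * (tt + 1.1) * (100 - rh) * el[month] * 1e-6
  p0 + 100 * k
}

oracle_dc <- function(dc0, temp, rain, month) {
  fl <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)
  d0 <- dc0
  if (rain > 2.8) {
    rd <- 0.83 * rain - 1.27
    qo <- 800 * exp(-d0 / 400)
    qr <- qo + 3.937 * rd
    dr <- 400 * log(800 / qr)
    if (dr < 0) dr <- 0
    d0 <- dr
  }
  tt <- temp
  if (tt < -2.8) tt <- -2.8
  v <- 0.36 * (tt + 2.8) + fl[month]
  if (v < 0) v <- 0
  d0 + 0.5 * v
}

oracle_isi <- function(ffmc, wind) {
  m <- 147.27723 * (101 - ffmc) / (59.5 + ffmc)
  fw <- exp(0.05039 * wind)
  ff <- 91.9 * exp(-0.1386 * m) * (1 + m^5.31 / 4.93e7)
  0.208 * fw * ff
}

oracle_bui <- function(dmc, dc) {
  if (dmc + 0.4 * dc <= 0) return(0)
  if (dmc <= 0.4 * dc) {
    u <- 0.8 * dmc * dc / (dmc + 0.4 * dc)
  } else {
    u <- dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) *
      (0.92 + (0.0114 * dmc)^1.7)
  }
  if (u < 0) u <- 0
  u
}

# One oracle day: codes first, then indices from the updated codes.
oracle_step <- function(ffmc0, dmc0, dc0, temp, rh, wind, rain, month) {
  f <- oracle_ffmc(ffmc0, temp, rh, wind, rain)
  p <- oracle_dmc(dmc0, temp, rh, rain, month)
  d <- oracle_dc(dc0, temp, rain, month)
  c(ffmc = f, dmc = p, dc = d,
    isi = oracle_isi(f, wind), bui = oracle_bui(p, d))
}

# Random but physically valid weather days, for parameterized checks.
random_weather <- function(n) {
  tibble::tibble(
    tmax_c = runif(n, -20, 38),
    rh_pct = runif(n, 5, 100),
    wind_kmh = runif(n, 0, 60),
    rain_mm = ifelse(runif(n) < 0.35, rexp(n, 1 / 6), 0),
    month = sample(1:12, n, replace = TRUE)
  )
}
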