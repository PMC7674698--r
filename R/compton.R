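# Compton (incoherent) scattering kinematics and sampling.

#' Compton-scattered photon energy at a given angle
#'
#' The Compton relation `E' = E / (1 + (E/mec2)(1 - cos theta))`.
#'
#' @param energy_mev Incident photon energy (MeV).
#' @param cos_theta Cosine of the polar scattering angle.
#' @return Scattered photon energy (MeV).
#' @export
#' @examples
#' compton_energy(0.1405, cos(pi))  # 180-degree backscatter: 0.0906 MeV
compton_energy <- function(energy_mev, cos_theta) {
  mec2 <- dose_constants()$electron_rest_mev
  energy_mev / (1 + (energy_mev / mec2) * (1 - cos_theta))
}

#' Sample Compton scattering events from the Klein-Nishina distribution
#'
#' Kahn's rejection method: the polar angle is drawn from the Klein-Nishina
#' differential cross-section for a free electron; the scattered energy
#' follows from the Compton relation. Uses R's random number stream.
#'
#' @param energy_mev Incident photon energy (MeV), scalar.
#' @param n Number of scattering events to sample.
#' @return data.frame with columns `energy_mev` (scattered photon energy),
#'   `cos_theta` and `theta` (polar angle, radians).
#' @export
#' @examples
#' set.seed(7)
#' s <- compton_scatter(0.1405, 1000)
#' mean(s$cos_theta)
compton_scatter <- function(energy_mev, n = 1) {
  stopifnot(energy_mev > 0, n >= 1)
  a <- energy_mev / dose_constants()$electron_rest_mev
  x <- numeric(n)                       # x = E/E'
  todo <- seq_len(n)
  p_branch <- (1 + 2 * a) / (9 + 2 * a)
  while (length(todo)) {
    r1 <- stats::runif(length(todo))
    r2 <- stats::runif(length(todo))
    r3 <- stats::runif(length(todo))
    b1 <- r1 <= p_branch
    xt <- numeric(length(todo))
    ok <- logical(length(todo))
    xt[b1] <- 1 + 2 * a * r2[b1]
    ok[b1] <- r3[b1] <= 4 * (1 / xt[b1] - 1 / xt[b1]^2)
    xt[!b1] <- (1 + 2 * a) / (1 + 2 * a * r2[!b1])
    ct <- 1 - (xt[!b1] - 1) / a
    ok[!b1] <- r3[!b1] <= 0.5 * (ct^2 + 1 / xt[!b1])
    x[todo[ok]] <- xt[ok]
    todo <- todo[!ok]
  }
  cos_theta <- 1 - (x - 1) / a
  data.frame(energy_mev = energy_mev / x, cos_theta = cos_theta,
             theta = acos(pmin(1, pmax(-1, cos_theta))))
}

#' Klein-Nishina differential cross-section (unnormalized)
#'
#' Angular density proportional to `(E'/E)^2 (E'/E + E/E' - sin^2 theta)`,
#' used as the independent reference when validating the sampler.
#'
#' @param energy_mev Incident photon energy (MeV).
#' @param cos_theta Cosine(s) of the polar angle.
#' @return Unnormalized differential cross-section per unit `cos_theta`.
#' @export
klein_nishina_pdf <- function(energy_mev, cos_theta) {
  r <- compton_energy(energy_mev, cos_theta) / energy_mev
  r^2 * (r + 1 / r - (1 - cos_theta^2))
}
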