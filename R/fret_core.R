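# Core Förster-transfer physics shared by the simulator and the analysis
# pipeline: dipole orientation factor, Förster-radius scaling, pairwise and
# multi-acceptor transfer efficiency, and the intensity <-> efficiency
# conversions used for donor dequenching.

#' Dipole geometry of a donor--acceptor pair
#'
#' Bundles the three unit vectors that determine the orientation factor
#' \eqn{\kappa^2}: the donor and acceptor transition dipoles and the direction
#' of the donor-to-acceptor separation.
#'
#' @param donor_dipole,acceptor_dipole Numeric length-3 unit vectors giving the
#'   transition dipole orientations (dimensionless).
#' @param separation_direction Numeric length-3 unit vector pointing from the
#'   donor to the acceptor.
#' @param tol Tolerance on the Euclidean norm of each vector (default `1e-9`).
#'
#' @return An object of class `dipole_geometry`.
#' @seealso [kappa_squared()]
#' @export
#' @examples
#' g <- dipole_geometry(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
#' kappa_squared(g)  # collinear alignment -> 4
dipole_geometry <- function(donor_dipole, acceptor_dipole, separation_direction,
                            tol = 1e-9) {
  vs <- list(donor_dipole = donor_dipole,
             acceptor_dipole = acceptor_dipole,
             separation_direction = separation_direction)
  for (nm in names(vs)) {
    v <- vs[[nm]]
    if (!is.numeric(v) || length(v) != 3L || anyNA(v)) {
      stop(sprintf("`%s` must be a numeric length-3 vector", nm), call. = FALSE)
    }
    if (abs(sqrt(sum(v^2)) - 1) > tol) {
      stop(sprintf("`%s` must have unit norm (within %g); got norm %.12f",
                   nm, tol, sqrt(sum(v^2))), call. = FALSE)
    }
  }
  structure(vs, class = "dipole_geometry")
}

#' Orientation factor kappa-squared
#'
#' Computes the dimensionless dipole orientation factor
#' \deqn{\kappa^2 = (\hat d_D \cdot \hat d_A -
#'   3\,(\hat d_D \cdot \hat R)(\hat d_A \cdot \hat R))^2,}
#' which ranges from 0 (orthogonal dipoles) through 1 ((anti-)parallel dipoles
#' perpendicular to the separation) to 4 (collinear alignment along the
#' separation axis). Its isotropic dynamic average is 2/3.
#'
#' @param geom A [dipole_geometry()] object.
#' @return A scalar in \[0, 4\].
#' @export
#' @examples
#' kappa_squared(dipole_geometry(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)))  # 1
kappa_squared <- function(geom) {
  if (!inherits(geom, "dipole_geometry")) {
    stop("`geom` must be a `dipole_geometry` object", call. = FALSE)
  }
  dD <- geom$donor_dipole
  dA <- geom$acceptor_dipole
  R  <- geom$separation_direction
  k <- sum(dD * dA) - 3 * sum(dD * R) * sum(dA * R)
  k^2
}

#' Donor--acceptor photophysics of a FRET pair
#'
#' Holds the Förster radius together with the photophysical quantities it is
#' derived from: donor quantum yield, spectral overlap integral, refractive
#' index of the medium, and the orientation factor. The default describes a
#' CFP/YFP pair under isotropic dynamic orientation averaging
#' (\eqn{\kappa^2 = 2/3}); the Förster radius of 4.9 nm keeps the pair
#' essentially blind (E < 5\%) beyond about 8 nm, the practical detection
#' limit for this fluorophore pair.
#'
#' @param r0 Förster radius in nm (> 0); the distance at which half of all
#'   donor excitations are transferred.
#' @param quantum_yield Donor fluorescence quantum yield, in (0, 1\].
#' @param overlap_integral Spectral overlap integral J in relative units (> 0).
#' @param refractive_index Refractive index n of the medium (>= 1).
#' @param kappa2 Orientation factor in \[0, 4\].
#'
#' @return An object of class `forster_pair`.
#' @export
forster_pair <- function(r0 = 4.9, quantum_yield = 0.4, overlap_integral = 1,
                         refractive_index = 1.4, kappa2 = 2 / 3) {
  stopifnot(is.numeric(r0), length(r0) == 1L)
  if (!(r0 > 0)) stop("`r0` must be > 0", call. = FALSE)
  if (!(quantum_yield > 0 && quantum_yield <= 1)) {
    stop("`quantum_yield` must lie in (0, 1]", call. = FALSE)
  }
  if (!(overlap_integral > 0)) stop("`overlap_integral` must be > 0", call. = FALSE)
  if (!(refractive_index >= 1)) stop("`refractive_index` must be >= 1", call. = FALSE)
  if (kappa2 < 0 || kappa2 > 4) stop("`kappa2` must lie in [0, 4]", call. = FALSE)
  structure(list(r0 = r0, quantum_yield = quantum_yield,
                 overlap_integral = overlap_integral,
                 refractive_index = refractive_index, kappa2 = kappa2),
            class = "forster_pair")
}

#' Rescale a Förster radius for changed photophysics
#'
#' The sixth power of the Förster radius is proportional to
#' \eqn{QY \cdot \kappa^2 \cdot J \cdot n^{-4}}. Given a reference pair and new
#' values of those quantities, the rescaled radius is
#' `reference$r0 * (ratio of the products)^(1/6)`. Because every parameter
#' enters under a sixth root, even large photophysical changes move the radius
#' only modestly.
#'
#' @param reference A [forster_pair()] providing the reference radius and
#'   photophysics.
#' @param new_QY,new_kappa2,new_J,new_n New quantum yield, orientation factor,
#'   overlap integral and refractive index. Defaults keep the reference value.
#'
#' @return The rescaled Förster radius in nm. `new_kappa2 = 0` returns 0 with
#'   a warning (no orientation coupling means no transfer at any distance).
#' @export
#' @examples
#' p <- forster_pair()
#' scale_forster_radius(p, new_kappa2 = 2 * p$kappa2)  # r0 * 2^(1/6)
scale_forster_radius <- function(reference,
                                 new_QY = reference$quantum_yield,
                                 new_kappa2 = reference$kappa2,
                                 new_J = reference$overlap_integral,
                                 new_n = reference$refractive_index) {
  if (!inherits(reference, "forster_pair")) {
    stop("`reference` must be a `forster_pair` object", call. = FALSE)
  }
  if (new_kappa2 == 0) {
    warning("kappa^2 = 0: no dipole coupling, Forster radius is 0")
    return(0)
  }
  if (new_QY <= 0 || new_kappa2 < 0 || new_J <= 0 || new_n <= 0) {
    stop("photophysical parameters must be strictly positive", call. = FALSE)
  }
  if (new_kappa2 > 4) stop("`new_kappa2` must lie in (0, 4]", call. = FALSE)
  ratio <- (new_QY * new_kappa2 * new_J * new_n^-4) /
    (reference$quantum_yield * reference$kappa2 *
       reference$overlap_integral * reference$refractive_index^-4)
  reference$r0 * ratio^(1 / 6)
}

#' Pairwise transfer efficiency at a given distance
#'
#' Energy-transfer efficiency of a single donor--acceptor pair,
#' \deqn{E = \frac{1}{1 + (r/r_0)^6},}
#' strictly decreasing in the separation `r` and exactly 0.5 at `r = r0`.
#'
#' @param r Donor--acceptor distance(s) in nm (>= 0); vectorised.
#' @param r0 Förster radius in nm (> 0).
#' @return Transfer efficiency as a fraction in (0, 1\].
#' @export
#' @examples
#' pair_efficiency(4.9, 4.9)      # 0.5
#' pair_efficiency(9.8, 4.9)      # 1/65
pair_efficiency <- function(r, r0) {
  if (!is.numeric(r0) || length(r0) != 1L || !(r0 > 0)) {
    stop("`r0` must be a single positive number", call. = FALSE)
  }
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  1 / (1 + (r / r0)^6)
}

#' Transfer efficiency of a donor facing several acceptors
#'
#' When several unbleached acceptors lie within transfer range of one donor,
#' each contributes an independent de-excitation channel with rate
#' \eqn{(r_0/r_i)^6} relative to the donor's intrinsic decay. The total
#' efficiency under these competing rates is
#' \deqn{E = \frac{S}{1 + S}, \qquad S = \sum_i s_i\,(r_0/r_i)^6,}
#' which reduces to [pair_efficiency()] for a single acceptor and never
#' decreases when an acceptor is added. An empty distance vector (no acceptor
#' in range) gives 0.
#'
#' @param distances Numeric vector of donor-to-acceptor distances in nm (all
#'   > 0); may be empty.
#' @param r0 Förster radius in nm (> 0).
#' @param rate_scale Optional per-acceptor multiplier \eqn{s_i} on the transfer
#'   rate (e.g. \eqn{\kappa_i^2 / \langle\kappa^2\rangle} for a statically
#'   reoriented pair); recycled against `distances`. Default 1.
#' @return Transfer efficiency as a fraction in \[0, 1).
#' @export
#' @examples
#' multi_acceptor_efficiency(c(4.9, 4.9), 4.9)  # S = 2 -> 2/3
multi_acceptor_efficiency <- function(distances, r0, rate_scale = 1) {
  if (!is.numeric(r0) || length(r0) != 1L || !(r0 > 0)) {
    stop("`r0` must be a single positive number", call. = FALSE)
  }
  if (length(distances) == 0L) return(0)
  if (any(distances <= 0)) stop("all `distances` must be > 0", call. = FALSE)
  if (any(rate_scale < 0)) stop("`rate_scale` must be >= 0", call. = FALSE)
  S <- sum(rate_scale * (r0 / distances)^6)
  S / (1 + S)
}

#' Donor intensity under quenching by energy transfer
#'
#' Energy transfer quenches the donor: at efficiency `E`, a donor that would
#' emit `I_unquenched` counts emits `I_unquenched * (1 - E)`. This is the
#' simulator-side inverse of [efficiency_from_intensities()].
#'
#' @param I_unquenched Unquenched donor intensity (>= 0); vectorised.
#' @param E Transfer efficiency as a fraction in \[0, 1); vectorised.
#' @return Quenched intensity, same length as the recycled inputs.
#' @export
#' @examples
#' quenched_intensity(100, 0.2)  # 80
quenched_intensity <- function(I_unquenched, E) {
  if (any(I_unquenched < 0)) stop("`I_unquenched` must be >= 0", call. = FALSE)
  if (any(E < 0) || any(E >= 1)) stop("`E` must lie in [0, 1)", call. = FALSE)
  I_unquenched * (1 - E)
}

#' Transfer efficiency from donor intensities before/after acceptor bleaching
#'
#' Acceptor photobleaching removes the transfer channel, dequenching the
#' donor. With donor intensity `I_before` while the acceptor is intact and
#' `I_after` once it is destroyed, the efficiency is
#' \deqn{E = \frac{I_{after} - I_{before}}{I_{after}}.}
#' Composition with [quenched_intensity()] is the identity on E in the
#' noise-free case. Negative values (donor brighter before bleaching) are
#' preserved; they arise from noise in real data.
#'
#' @param I_before Donor intensity before acceptor bleaching (quenched).
#' @param I_after Donor intensity after acceptor bleaching (dequenched, > 0).
#' @return Efficiency as a fraction (may be negative); vectorised.
#' @export
#' @examples
#' efficiency_from_intensities(80, 100)  # 0.2
efficiency_from_intensities <- function(I_before, I_after) {
  if (any(I_after <= 0)) stop("`I_after` must be > 0", call. = FALSE)
  (I_after - I_before) / I_after
}

#' Sample the orientation factor from the static isotropic distribution
#'
#' Draws \eqn{\kappa^2} values for pairs whose dipoles are frozen in random
#' orientations (the static isotropic regime, relevant after chemical
#' fixation): both dipole directions are sampled uniformly on the sphere and
#' the orientation factor is evaluated against a fixed separation axis. The
#' distribution has mean 2/3 but is strongly skewed toward small values.
#'
#' @param n Number of samples.
#' @return Numeric vector of `n` draws in \[0, 4\].
#' @export
sample_kappa2_static <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  unit_rows <- function(n) {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  }
  dD <- unit_rows(n)
  dA <- unit_rows(n)
  # separation axis fixed at z by isotropy
  (rowSums(dD * dA) - 3 * dD[, 3] * dA[, 3])^2
}
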