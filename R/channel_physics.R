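#' Rectangular culture-channel geometry
#'
#' Geometry of the microfluidic culture channel: a straight cuboid duct of
#' length `length_L`, width `width_w` and height `height_h`, with a
#' gas-permeable membrane of thickness `membrane_thickness_e` on top and a
#' bacterial monolayer of height `monolayer_height` on the floor. Defaults
#' correspond to a 10 mm x 1 mm x 150 um channel with a 150 um membrane and
#' a 3 um monolayer. All lengths in metres.
#'
#' @param length_L channel length (m).
#' @param width_w channel width (m); must exceed the height (wide, flat duct).
#' @param height_h channel height (m).
#' @param membrane_thickness_e membrane thickness (m).
#' @param monolayer_height height of the attached cell monolayer (m); shear
#'   is averaged over this near-wall layer.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(length_L = 10e-3, width_w = 1e-3,
                             height_h = 1.5e-4, membrane_thickness_e = 1.5e-4,
                             monolayer_height = 3e-6) {
  dims <- c(length_L = length_L, width_w = width_w, height_h = height_h,
            membrane_thickness_e = membrane_thickness_e,
            monolayer_height = monolayer_height)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid geometry: all channel dimensions must be strictly positive")
  if (monolayer_height >= height_h)
    stop("invalid geometry: monolayer_height must be smaller than height_h")
  if (width_w <= height_h)
    stop("invalid geometry: width_w must exceed height_h (wide-channel duct)")
  structure(as.list(dims), class = "channel_geometry")
}

#' Flow regime descriptor
#'
#' A named flow condition characterised primarily by its near-wall shear
#' rate; the wall shear stress follows as viscosity x shear rate. The
#' default viscosity is that of water at 37 degrees C, 0.691 mPa s.
#'
#' @param name regime label (e.g. "ulow", "low", "med", "high").
#' @param shear_rate near-wall shear rate (1/s).
#' @param viscosity_mu dynamic viscosity (mPa s).
#' @param flow_rate_Q optional volumetric flow rate (m^3/s).
#' @return An object of class `flow_regime` with fields `name`,
#'   `shear_rate`, `shear_stress` (mPa), `viscosity_mu`, `flow_rate_Q`.
#' @export
flow_regime <- function(name, shear_rate, viscosity_mu = 0.691,
                        flow_rate_Q = NA_real_) {
  if (!is.finite(shear_rate) || shear_rate < 0)
    stop("invalid parameter: shear_rate must be >= 0")
  if (!is.finite(viscosity_mu) || viscosity_mu <= 0)
    stop("invalid parameter: viscosity_mu must be > 0")
  structure(list(name = as.character(name), shear_rate = shear_rate,
                 shear_stress = shear_stress(shear_rate, viscosity_mu),
                 viscosity_mu = viscosity_mu, flow_rate_Q = flow_rate_Q),
            class = "flow_regime")
}

#' The four reference shear regimes
#'
#' Shear rates of the four experimental flow regimes (ultra-low, low,
#' medium, high) and their wall shear stresses at 37 degrees C.
#'
#' @param viscosity_mu dynamic viscosity (mPa s).
#' @return A data.frame with columns `name`, `shear_rate` (1/s) and
#'   `shear_stress` (mPa).
#' @export
reference_regimes <- function(viscosity_mu = 0.691) {
  rates <- c(ulow = 7, low = 29, med = 72, high = 116)
  data.frame(name = names(rates), shear_rate = unname(rates),
             shear_stress = shear_stress(unname(rates), viscosity_mu),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Fourier-series solution for pressure-driven Stokes flow in a rectangular
## duct. Coordinates: z in [0, h] vertical, y in [-w/2, w/2] lateral.
## v(y, z) = (4 h^2 G / (pi^3 mu)) sum_{n odd} n^-3
##             [1 - cosh(n pi y / h)/cosh(n pi w / (2h))] sin(n pi z / h)
## Viscosity cancels once the pressure gradient is eliminated in favour of
## the flow rate Q, so it is set to 1 internally.
duct_series_terms <- function(geometry, rel_tol = 1e-6, max_terms = 2000L) {
  h <- geometry$height_h; w <- geometry$width_w
  n <- seq(1L, 2L * max_terms - 1L, by = 2L)
  beta <- n * pi * w / (2 * h)
  # flow-rate bracket: Q = G h^3 w / 12 * [1 - (192 h / (pi^5 w)) sum tanh(beta)/n^5]
  q_terms <- (192 * h / (pi^5 * w)) * tanh(beta) / n^5
  # mid-width wall shear series coefficients: dv/dz(0, y=0) per unit G
  s_terms <- (4 * h / pi^2) * (1 - 1 / cosh(beta)) / n^2
  cum <- cumsum(s_terms)
  keep <- which(s_terms[-1] >= rel_tol * abs(cum[-1]))
  n_keep <- if (length(keep)) min(max(keep) + 1L, max_terms) else 1L
  list(n = n[seq_len(n_keep)], q_bracket = 1 - sum(q_terms))
}

duct_pressure_gradient <- function(geometry, flow_rate, terms) {
  h <- geometry$height_h; w <- geometry$width_w
  flow_rate / (h^3 * w / 12 * terms$q_bracket)
}

#' Velocity profile at mid-width of a rectangular duct
#'
#' Stokes (creeping) flow in a straight cuboid channel driven by a given
#' volumetric flow rate, evaluated on a uniform vertical grid at mid-width.
#' The truncated Fourier-series duct solution is used; terms are added
#' until the next term changes the mid-width wall shear by less than a
#' relative 1e-6.
#'
#' @param geometry a [channel_geometry()].
#' @param flow_rate volumetric flow rate (m^3/s), >= 0.
#' @param n number of grid points over `[0, h]`.
#' @return data.frame with columns `z` (m) and `v` (m/s); no-slip at both
#'   walls, `v(0) = v(h) = 0`.
#' @export
duct_velocity_profile <- function(geometry, flow_rate, n = 201L) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (!is.finite(flow_rate) || flow_rate < 0)
    stop("invalid parameter: flow_rate must be >= 0")
  z <- seq(0, geometry$height_h, length.out = n)
  data.frame(z = z, v = duct_velocity(geometry, flow_rate, y = 0, z = z))
}

#' Evaluate the duct velocity field
#'
#' Pointwise velocity of the rectangular-duct Stokes solution, vectorised
#' over `y` and `z` (outer product when both are vectors).
#'
#' @inheritParams duct_velocity_profile
#' @param y lateral coordinates (m), in `[-w/2, w/2]`.
#' @param z vertical coordinates (m), in `[0, h]`.
#' @return Matrix of velocities (m/s), `length(y)` rows x `length(z)` columns
#'   (dropped to a vector when one of the inputs is scalar).
#' @export
duct_velocity <- function(geometry, flow_rate, y, z) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (!is.finite(flow_rate) || flow_rate < 0)
    stop("invalid parameter: flow_rate must be >= 0")
  h <- geometry$height_h; w <- geometry$width_w
  terms <- duct_series_terms(geometry)
  G <- duct_pressure_gradient(geometry, flow_rate, terms)
  n <- terms$n
  pref <- 4 * h^2 * G / pi^3
  # cosh(a)/cosh(b) with |a| <= b, computed in log space to avoid overflow
  a <- abs(outer(y, n) * (pi / h))
  b <- matrix(n * pi * w / (2 * h), length(y), length(n), byrow = TRUE)
  lat <- 1 - exp(a - b) * (1 + exp(-2 * a)) / (1 + exp(-2 * b))
  vert <- sin(outer(z, n) * (pi / h))
  v <- pref * (lat %*% (t(vert) / n^3))
  drop(v)
}

#' Near-wall shear rate averaged over the monolayer
#'
#' Vertical velocity gradient at mid-width averaged over the monolayer
#' height (`z` from 0 to `monolayer_height`), which for `v(0) = 0` equals
#' `v(monolayer_height)/monolayer_height`.
#'
#' @inheritParams duct_velocity_profile
#' @return Shear rate (1/s).
#' @export
wall_shear_rate <- function(geometry, flow_rate) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (!is.finite(flow_rate) || flow_rate < 0)
    stop("invalid parameter: flow_rate must be >= 0")
  if (geometry$monolayer_height >= geometry$height_h / 2)
    stop("invalid parameter: monolayer_height must be < h/2 for a near-wall average")
  if (flow_rate == 0) return(0)
  zm <- geometry$monolayer_height
  duct_velocity(geometry, flow_rate, y = 0, z = zm) / zm
}

#' Wall shear stress
#'
#' Newtonian constitutive relation: stress = viscosity x shear rate.
#' With viscosity in mPa s and shear rate in 1/s the stress is in mPa.
#'
#' @param shear_rate shear rate (1/s), >= 0; vectorised.
#' @param viscosity dynamic viscosity (mPa s); default water at 37 C.
#' @return Shear stress (mPa).
#' @export
shear_stress <- function(shear_rate, viscosity = 0.691) {
  if (any(!is.finite(shear_rate)) || any(shear_rate < 0))
    stop("invalid parameter: shear_rate must be >= 0")
  if (any(!is.finite(viscosity)) || any(viscosity <= 0))
    stop("invalid parameter: viscosity must be > 0")
  viscosity * shear_rate
}

#' Nutrient and oxygen transport parameters
#'
#' Concentrations, per-cell consumption rates and transport scales used in
#' the Damkohler estimates. The oxygen diffusivity through the membrane
#' (`D_O2_pdms`) has no canonical value here and must be supplied
#' explicitly; a literature value for oxygen in PDMS is around
#' 3.4e-9 m^2/s.
#'
#' @param c_O2 dissolved oxygen concentration (kg/m^3).
#' @param c_glu glucose concentration (kg/m^3).
#' @param mu_O2 per-cell oxygen consumption rate (kg/cell/s). Note: the
#'   symbol mu is used for viscosity elsewhere; consumption fields carry a
#'   species suffix to disambiguate.
#' @param mu_glu per-cell glucose consumption rate (kg/cell/s).
#' @param B attached-cell surface density (cell/m^2).
#' @param v_mean mean flow velocity in the channel (m/s).
#' @param D_O2_pdms oxygen diffusivity through the membrane (m^2/s);
#'   required, no default.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(c_O2 = 6.6e-3, c_glu = 2e-3, mu_O2 = 7e-21,
                             mu_glu = 5e-20, B, v_mean, D_O2_pdms = NULL) {
  vals <- c(c_O2 = c_O2, c_glu = c_glu, mu_O2 = mu_O2, mu_glu = mu_glu,
            B = B, v_mean = v_mean)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid parameter: transport parameters must be strictly positive")
  structure(list(c_O2 = c_O2, c_glu = c_glu, mu_O2 = mu_O2, mu_glu = mu_glu,
                 B = B, v_mean = v_mean, D_O2_pdms = D_O2_pdms),
            class = "transport_params")
}

#' Damkohler numbers for oxygen and nutrient delivery
#'
#' Ratios of a transport time to the consumption time
#' `tau_c = c h / (mu B)`: for oxygen the membrane diffusion time
#' `tau_D = e^2 / D`, for glucose the advection time `tau_a = L / v`.
#' Values well below 1 mean delivery outpaces consumption (no limitation).
#'
#' @param params a [transport_params()]; `D_O2_pdms` must be set.
#' @param geometry a [channel_geometry()].
#' @param check_density warn when `B` is outside the experimental range
#'   `[1e10, 2e11]` cell/m^2.
#' @return Named list `Da_O2`, `Da_nutrient` (dimensionless).
#' @export
damkohler_numbers <- function(params, geometry, check_density = TRUE) {
  stopifnot(inherits(params, "transport_params"),
            inherits(geometry, "channel_geometry"))
  if (is.null(params$D_O2_pdms))
    stop("configuration error: D_O2_pdms must be supplied explicitly ",
         "(no default oxygen diffusivity is assumed)")
  if (check_density && (params$B < 1e10 || params$B > 2e11))
    warning("surface density B outside the experimental range [1e10, 2e11] cell/m^2")
  h <- geometry$height_h
  tau_D <- geometry$membrane_thickness_e^2 / params$D_O2_pdms
  tau_c_O2 <- params$c_O2 * h / (params$mu_O2 * params$B)
  tau_a <- geometry$length_L / params$v_mean
  tau_c_glu <- params$c_glu * h / (params$mu_glu * params$B)
  list(Da_O2 = tau_D / tau_c_O2, Da_nutrient = tau_a / tau_c_glu)
}
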