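#' Adhesion geometry
#'
#' Static geometry and adhesion computations: the surface-tension spring and
#' sphere discretization of the single-body model, per-partition wall-contact
#' areas and platelet-derived adhesion forces of the chain model, and the
#' equal-area partitioning of a clot moulded into a stenosed artery.
#'
#' @name adhesion
NULL

#' Surface-tension spring constant
#'
#' The clot is bound to the wall by surface tension, a force per unit length
#' of contact; numerically the tension equals the spring constant K that the
#' model uses to measure the force at the clot face. The contact length
#' defaults to the artery circumference `pi * D`.
#'
#' @param F force acting on the contact (N).
#' @param contact_perimeter contact line length (m).
#' @return spring constant K = F / l (N/m).
#' @examples
#' surface_tension_spring(0.01, pi * 2.5e-3) # ~1.27 N/m
#' @export
surface_tension_spring <- function(F, contact_perimeter) {
  if (!is.numeric(contact_perimeter) || contact_perimeter <= 0) {
    stop("contact_perimeter must be > 0", call. = FALSE)
  }
  F / contact_perimeter
}

#' Number of adhesion anchor spheres along the clot
#'
#' One anchor sphere per `spacing` of clot length (0.1 mm by default), so a
#' 1.0 cm clot has 100 anchors and a 5.0 cm clot 500.
#'
#' @param length clot length (m).
#' @param spacing anchor spacing (m).
#' @return integer sphere count (at least 1).
#' @export
sphere_count <- function(length, spacing = 1e-4) {
  if (!is.numeric(length) || length <= 0 || !is.numeric(spacing) ||
      spacing <= 0) {
    stop("length and spacing must be > 0", call. = FALSE)
  }
  max(1L, as.integer(round(length / spacing)))
}

#' Equivalent spring of n identical anchors
#'
#' The clot behaves as a rigid body held by n identical anchor springs, and
#' the model replaces them with a single measurement spring `K/n` (the
#' printed rule for this model). The conventional parallel-spring combination
#' `K*n` is available with `mode = "parallel_sum"`.
#'
#' @param K single-anchor spring constant (N/m).
#' @param n number of anchors (>= 1).
#' @param mode `"divide"` (default) or `"parallel_sum"`.
#' @return equivalent spring constant (N/m).
#' @export
equivalent_spring <- function(K, n, mode = c("divide", "parallel_sum")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (mode == "divide") K / n else K * n
}

#' Measurement-spring displacement at the movement threshold
#'
#' Displacement of the equivalent spring when loaded with the threshold
#' force; the clot is released (and friction switches from static to
#' dynamic) once the measurement spring has stretched this far.
#'
#' @param F_threshold threshold force (N), 0.01 N by default in the model.
#' @param K_eq equivalent spring constant (N/m).
#' @return displacement x = F / K_eq (m).
#' @export
release_displacement <- function(F_threshold, K_eq) {
  if (!is.numeric(K_eq) || K_eq <= 0) stop("K_eq must be > 0", call. = FALSE)
  F_threshold / K_eq
}

#' Lateral wall-contact area per partition (cylindrical clot)
#'
#' @param artery_diameter artery diameter (m).
#' @param clot_length clot length (m).
#' @param n_partitions number of partitions.
#' @return contact area `pi * D * L / n` (m^2) of each partition.
#' @export
lateral_contact_area <- function(artery_diameter, clot_length, n_partitions) {
  if (!is.numeric(artery_diameter) || artery_diameter <= 0 ||
      !is.numeric(clot_length) || clot_length <= 0 ||
      !is.numeric(n_partitions) || n_partitions < 1) {
    stop("artery_diameter, clot_length must be > 0 and n_partitions >= 1",
         call. = FALSE)
  }
  pi * artery_diameter * clot_length / n_partitions
}

#' Number of wall-contact platelets on a contact patch
#'
#' `fp * SA / MPA`: the platelet fraction of the contact area divided by the
#' mean platelet area. The count is kept real-valued; it is only ever used
#' multiplicatively.
#'
#' @param fp platelet fraction of the clot.
#' @param SA wall-contact area (m^2).
#' @param MPA mean platelet area (m^2).
#' @return platelet count (real-valued).
#' @export
platelet_count <- function(fp, SA, MPA) {
  if (!is.numeric(MPA) || MPA <= 0) stop("MPA must be > 0", call. = FALSE)
  fp * SA / MPA
}

#' Adhesion force of a contact patch
#'
#' @param n_platelets platelet count in wall contact.
#' @param F_platelet single platelet-wall bond force (N).
#' @return adhesion force (N).
#' @export
partition_adhesion_force <- function(n_platelets, F_platelet) {
  n_platelets * F_platelet
}

# adhesion force for a given contact area, chaining the platelet model
.area_adhesion <- function(area, clot) {
  partition_adhesion_force(platelet_count(clot$fp, area, clot$MPA),
                           clot$F_platelet)
}

#' Stenosis radius profile
#'
#' Returns the local lumen radius as a function of the axial artery
#' coordinate. Without stenosis the profile is the constant artery radius.
#' The built-in stenosed profile is a cosine bump centred on the clot
#' extent \[0, L\]:
#' `r(x) = R * (1 - severity * (1 + cos(2*pi*(x - L/2)/L)) / 2)`,
#' which narrows the radius by `severity * R` at the bump apex and returns
#' to the full radius at (and beyond) both ends of the clot.
#'
#' @param artery an [artery_spec()].
#' @param clot a [clot_spec()] (sets the axial extent of the bump).
#' @return vectorized function of the axial coordinate (m) returning the
#'   radius (m).
#' @export
stenosis_profile <- function(artery, clot) {
  R <- artery$diameter / 2
  st <- artery$stenosis
  if (is.null(st)) {
    return(function(x) rep_len(R, length(x)))
  }
  if (!is.null(st$profile)) {
    prof <- st$profile
    return(function(x) {
      r <- prof(x)
      if (any(r <= 0) || any(r > R + 1e-12)) {
        stop("stenosis profile must satisfy 0 < r(x) <= artery radius",
             call. = FALSE)
      }
      r
    })
  }
  a <- st$severity
  L <- clot$length
  function(x) {
    inside <- x >= 0 & x <= L
    r <- rep_len(R, length(x))
    r[inside] <- R * (1 - a * (1 + cos(2 * pi * (x[inside] - L / 2) / L)) / 2)
    r
  }
}

# dense-grid cumulative integrals of the contact-area and volume densities
.profile_cumulatives <- function(profile, x_lo, x_hi, n_grid = 20000L) {
  xs <- seq(x_lo, x_hi, length.out = n_grid + 1L)
  r <- profile(xs)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("stenosis profile must be positive over the clot extent",
         call. = FALSE)
  }
  list(x = xs,
       area = as.numeric(pracma::cumtrapz(xs, 2 * pi * r)),
       volume = as.numeric(pracma::cumtrapz(xs, pi * r^2)))
}

.partition_frame <- function(index, x_start, x_end, area, volume, mass,
                             adhesion_force) {
  structure(data.frame(index = index, x_start = x_start, x_end = x_end,
                       area = area, volume = volume, mass = mass,
                       adhesion_force = adhesion_force),
            class = c("clot_partitions", "data.frame"))
}

#' Partition a clot into equal-adhesion segments
#'
#' For a cylindrical clot in a straight artery the partitions are uniform:
#' equal spans, areas `pi*D*L/n`, volumes and masses. For a stenosed artery
#' the clot is moulded to the lumen and [partition_stenosed_clot()] is used.
#'
#' @param artery an [artery_spec()].
#' @param clot a [clot_spec()].
#' @param n number of partitions (defaults to `clot$n_partitions`).
#' @return a `clot_partitions` data frame with columns index, x_start,
#'   x_end (m, axial span from the proximal face), area (m^2), volume (m^3),
#'   mass (kg) and adhesion_force (N).
#' @examples
#' art <- artery_spec(2.5e-3)
#' cl <- clot_spec(0.03, 2.5e-3, 1.25e-3, n_partitions = 3)
#' partition_clot(art, cl)
#' @export
partition_clot <- function(artery, clot, n = clot$n_partitions) {
  if (!is.null(artery$stenosis)) {
    return(partition_stenosed_clot(artery, clot, n))
  }
  L <- clot$length
  edges <- seq(0, L, length.out = n + 1L)
  area <- rep(lateral_contact_area(artery$diameter, L, n), n)
  volume <- rep(pi * (clot$diameter / 2)^2 * L / n, n)
  .partition_frame(seq_len(n) - 1L, edges[-(n + 1L)], edges[-1L],
                   area, volume, clot$total_mass / n,
                   .area_adhesion(area, clot))
}

#' Partition a clot moulded into a stenosed artery
#'
#' Cut points along the axis are chosen so that every partition has the same
#' wall-contact area, computed by inverting the cumulative integral of the
#' contact-area density `2*pi*r(x)` on a dense grid. Equal volumes
#' (`integral of pi*r(x)^2`) generally cannot hold simultaneously for the
#' same cuts; equal area is primary because adhesion is area-driven, and a
#' warning reports the relative volume spread when it exceeds 0.1%.
#' Masses are `total_mass / n` and adhesion forces follow from the platelet
#' model applied to each partition's area.
#'
#' @inheritParams partition_clot
#' @param n_grid grid resolution of the cumulative integrals.
#' @return a `clot_partitions` data frame (see [partition_clot()]).
#' @export
partition_stenosed_clot <- function(artery, clot, n = clot$n_partitions,
                                    n_grid = 20000L) {
  profile <- stenosis_profile(artery, clot)
  cum <- .profile_cumulatives(profile, 0, clot$length, n_grid)
  A_tot <- cum$area[length(cum$area)]
  targets <- A_tot * seq_len(n - 1L) / n
  # cumulative area is strictly increasing, so linear inverse interpolation
  cuts <- if (n > 1L) {
    stats::approx(cum$area, cum$x, xout = targets, ties = "ordered")$y
  } else numeric(0)
  edges <- c(0, cuts, clot$length)
  area_at <- stats::approxfun(cum$x, cum$area)
  vol_at <- stats::approxfun(cum$x, cum$volume)
  area <- diff(area_at(edges))
  volume <- diff(vol_at(edges))
  if (n > 1L) {
    spread <- (max(volume) - min(volume)) / mean(volume)
    if (spread > 1e-3) {
      warning(sprintf(paste0("equal-area cuts leave a %.2f%% relative ",
                             "volume spread across partitions"),
                      100 * spread), call. = FALSE)
    }
  }
  .partition_frame(seq_len(n) - 1L, edges[-(n + 1L)], edges[-1L],
                   area, volume, clot$total_mass / n,
                   .area_adhesion(area, clot))
}

#' Recompute partition geometry after the clot has moved
#'
#' When the clot slides a distance `displacement` toward the device, each
#' still-attached partition faces a shifted stretch of the artery wall; its
#' contact area, volume and adhesion force are re-integrated over the
#' shifted span (the stenosis profile is a property of the artery and stays
#' put; the lumen returns to the full radius outside the original bump).
#' Partitions whose adhesion has already been released keep zero adhesion.
#'
#' @param partitions a `clot_partitions` data frame.
#' @param displacement clot displacement toward the device (m, >= 0).
#' @param artery an [artery_spec()].
#' @param clot a [clot_spec()].
#' @return updated `clot_partitions` data frame.
#' @export
repartition_after_motion <- function(partitions, displacement, artery, clot) {
  stopifnot(displacement >= 0)
  if (displacement == 0) return(partitions)
  profile <- stenosis_profile(artery, clot)
  for (i in seq_len(nrow(partitions))) {
    lo <- partitions$x_start[i] - displacement
    hi <- partitions$x_end[i] - displacement
    cum <- .profile_cumulatives(profile, lo, hi,
                                n_grid = max(200L, ceiling((hi - lo) / 1e-5)))
    partitions$area[i] <- cum$area[length(cum$area)]
    partitions$volume[i] <- cum$volume[length(cum$volume)]
    if (partitions$adhesion_force[i] > 0) {
      partitions$adhesion_force[i] <- .area_adhesion(partitions$area[i], clot)
    }
  }
  partitions
}

#' Adhesion summary of the single-body model
#'
#' @param scenario a [scenario()].
#' @return list with the surface-tension spring `K_surface` (N/m), anchor
#'   count `n_spheres`, equivalent spring `K_eq` (N/m) and the
#'   `release_displacement` (m) at the movement threshold.
#' @export
adhesion_summary <- function(scenario) {
  K <- surface_tension_spring(scenario$mech$F_move_threshold,
                              pi * scenario$artery$diameter)
  n <- sphere_count(scenario$clot$length, scenario$clot$sphere_spacing)
  K_eq <- equivalent_spring(K, n, scenario$mech$eq_spring_mode)
  list(K_surface = K, n_spheres = n, K_eq = K_eq,
       release_displacement =
         release_displacement(scenario$mech$F_move_threshold, K_eq))
}
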