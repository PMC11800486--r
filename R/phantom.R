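#' Lesion specification
#'
#' Parameterises one white-matter lesion as a spherical demyelinated core with
#' an optional paramagnetic (iron) rim occupying a spherical-cap fraction of
#' the surrounding annulus, and an optional central vein modelled as a
#' cylinder through the lesion centre.
#'
#' @param center numeric length 3, lesion centre in mm (world frame, grid
#'   centred at the origin).
#' @param core_radius core radius, mm (> 0).
#' @param core_chi core susceptibility offset over background, ppm.
#' @param rim_chi rim susceptibility offset, ppm (>= 0 when a rim exists).
#' @param rim_thickness radial rim thickness, mm (0 = no rim).
#' @param rim_coverage fraction of the full solid angle covered by the rim
#'   cap, in `[0, 1]`. 1 is a complete shell.
#' @param rim_axis unit 3-vector: symmetry axis of the rim cap (ignored when
#'   `rim_coverage` is 1 or `rim_thickness` is 0).
#' @param vein optional list with fields `axis` (unit 3-vector), `radius`
#'   (mm) and `chi` (ppm) describing a central vein.
#' @param class_label optional character tag carried into truth tables.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, core_radius, core_chi = 0.02,
                        rim_chi = 0, rim_thickness = 0, rim_coverage = 1,
                        rim_axis = c(0, 0, 1), vein = NULL,
                        class_label = NA_character_) {
  if (core_radius <= 0) stop("core_radius must be > 0")
  if (rim_thickness < 0) stop("rim_thickness must be >= 0")
  if (rim_coverage < 0 || rim_coverage > 1) stop("rim_coverage must be in [0, 1]")
  if (rim_thickness > 0 && rim_chi < 0) stop("rim_chi must be >= 0 when a rim exists")
  if (!is.null(vein)) {
    stopifnot(is.list(vein), all(c("axis", "radius", "chi") %in% names(vein)),
              vein$radius > 0)
    vein$axis <- vein$axis / sqrt(sum(vein$axis^2))
  }
  structure(list(center = as.numeric(center), core_radius = core_radius,
                 core_chi = core_chi, rim_chi = rim_chi,
                 rim_thickness = rim_thickness, rim_coverage = rim_coverage,
                 rim_axis = as.numeric(rim_axis / sqrt(sum(rim_axis^2))),
                 vein = vein, class_label = class_label),
            class = "lesion_spec")
}

outer_radius <- function(lesion) lesion$core_radius + lesion$rim_thickness

#' Phantom specification
#'
#' A grid geometry plus a list of non-overlapping lesions and a uniform
#' background susceptibility. Overlap and out-of-bounds placement are
#' rejected here so that downstream voxelization is unambiguous.
#'
#' @param geometry a [grid_geometry()].
#' @param lesions list of [lesion_spec()] objects.
#' @param background_chi background susceptibility, ppm (reference 0).
#' @param seed integer seed recorded with the spec (used by noise synthesis
#'   downstream; the spec itself is deterministic).
#' @param margin_voxels minimum clearance between any lesion's outer surface
#'   and the grid boundary, in voxels (default 4).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry, lesions = list(), background_chi = 0,
                         seed = 1L, margin_voxels = 4) {
  stopifnot(inherits(geometry, "grid_geometry"))
  half_fov <- geometry$shape * geometry$voxel_size / 2
  margin <- margin_voxels * geometry$voxel_size
  for (i in seq_along(lesions)) {
    li <- lesions[[i]]
    if (any(abs(li$center) + outer_radius(li) > half_fov - margin))
      stop(sprintf("lesion %d extends outside the grid margin", i))
  }
  if (length(lesions) >= 2L) {
    for (i in seq_len(length(lesions) - 1L)) for (j in seq(i + 1L, length(lesions))) {
      d <- sqrt(sum((lesions[[i]]$center - lesions[[j]]$center)^2))
      if (d <= outer_radius(lesions[[i]]) + outer_radius(lesions[[j]]))
        stop(sprintf("lesions %d and %d overlap", i, j))
    }
  }
  structure(list(geometry = geometry, lesions = lesions,
                 background_chi = background_chi, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Voxelize a phantom into a susceptibility map
#'
#' Assigns each voxel by voxel-centre membership: vein chi inside a vein
#' cylinder, rim chi inside the rim annulus restricted to the coverage cap,
#' core chi inside the core, background elsewhere. The rim cap is the set of
#' annulus voxels whose direction from the lesion centre lies within a cone
#' about `rim_axis` whose solid angle is `rim_coverage` of the full sphere.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `susceptibility_map`: list with `values` (3D ppm
#'   array) and `geometry`.
#' @export
build_susceptibility_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  vals <- array(spec$background_chi, dim = g$shape)
  co <- voxel_coordinates(g)
  for (les in spec$lesions) {
    dx <- co$x - les$center[1]; dy <- co$y - les$center[2]; dz <- co$z - les$center[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    core <- r <= les$core_radius
    vals[core] <- spec$background_chi + les$core_chi
    if (les$rim_thickness > 0 && les$rim_coverage > 0) {
      ann <- r > les$core_radius & r <= outer_radius(les)
      if (les$rim_coverage < 1) {
        # cap solid angle fraction f = (1 - cos(theta_max)) / 2
        cos_max <- 1 - 2 * les$rim_coverage
        ax <- les$rim_axis
        ct <- (dx * ax[1] + dy * ax[2] + dz * ax[3]) / pmax(r, .Machine$double.eps)
        ann <- ann & ct >= cos_max
      }
      vals[ann] <- spec$background_chi + les$rim_chi
    }
    if (!is.null(les$vein)) {
      ax <- les$vein$axis
      proj <- dx * ax[1] + dy * ax[2] + dz * ax[3]
      perp2 <- pmax(dx^2 + dy^2 + dz^2 - proj^2, 0)
      vein_mask <- perp2 <= les$vein$radius^2 & r <= les$core_radius
      vals[vein_mask] <- spec$background_chi + les$vein$chi
    }
  }
  structure(list(values = vals, geometry = g), class = "susceptibility_map")
}

#' Iron-rim ground truth for a phantom
#'
#' A lesion is iron-positive when it carries a paramagnetic rim of nonzero
#' thickness and susceptibility covering at least `coverage_floor` of the
#' lesion circumference; this mirrors a histology reading that calls a lesion
#' iron+ when iron is present at the lesion periphery.
#'
#' @param spec a [phantom_spec()] (or a list of them, concatenated in order).
#' @param coverage_floor minimum rim coverage fraction for iron+, default 0.25.
#' @return data.frame (`truth_table`): `lesion_id`, `iron_rim_status`
#'   (`"iron+"`/`"iron-"`), `class_label`.
#' @export
ground_truth <- function(spec, coverage_floor = 0.25) {
  lesions <- if (inherits(spec, "phantom_spec")) spec$lesions
             else unlist(lapply(spec, function(p) p$lesions), recursive = FALSE)
  status <- vapply(lesions, function(l) {
    pos <- l$rim_thickness > 0 && l$rim_chi > 0 && l$rim_coverage >= coverage_floor
    if (pos) "iron+" else "iron-"
  }, character(1))
  labels <- vapply(lesions, function(l) l$class_label, character(1))
  out <- data.frame(lesion_id = seq_along(lesions),
                    iron_rim_status = status,
                    class_label = labels,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_table", class(out))
  out
}

#' Default per-class lesion parameter ranges for the cohort generator
#'
#' Susceptibility contrasts are literature-typical: a demyelinated core is
#' +0.04 to +0.10 ppm over normal-appearing white matter (loss of the
#' roughly -0.05 ppm myelin contribution plus variable diffuse iron), an
#' iron rim +0.10 to +0.20 ppm, a vein +0.30 ppm over a 0 ppm reference.
#' Scalar fields are fixed values; two-element fields are uniform sampling
#' ranges.
#'
#' @return named list of per-class parameter lists (`solid`, `rim`,
#'   `partial_rim`, `veined`).
#' @export
default_class_params <- function() {
  list(
    solid       = list(core_radius = c(2.5, 4.5), core_chi = c(0.04, 0.10),
                       rim_chi = 0, rim_thickness = c(0, 0), rim_coverage = c(1, 1)),
    rim         = list(core_radius = c(2.5, 4.5), core_chi = c(0.04, 0.10),
                       rim_chi = c(0.10, 0.20), rim_thickness = c(0.8, 1.2),
                       rim_coverage = c(1, 1)),
    partial_rim = list(core_radius = c(2.5, 4.5), core_chi = c(0.04, 0.10),
                       rim_chi = c(0.10, 0.20), rim_thickness = c(0.8, 1.2),
                       rim_coverage = c(0.3, 0.7)),
    veined      = list(core_radius = c(2.5, 4.5), core_chi = c(0.04, 0.10),
                       rim_chi = 0, rim_thickness = c(0, 0), rim_coverage = c(1, 1),
                       vein_radius = c(0.3, 0.5), vein_chi = 0.30)
  )
}

runif1 <- function(rng) {
  if (length(rng) == 1L || rng[1] == rng[2]) rng[1]
  else stats::runif(1, rng[1], rng[2])
}

#' Generate a lesion cohort with known ground truth
#'
#' Draws `n_per_class` lesions from each of the four lesion classes (solid
#' demyelinated core, full iron rim, partial iron rim, solid with central
#' vein), one lesion per phantom, placed near the grid centre with a small
#' random jitter. Reproducible for a fixed seed.
#'
#' @param n_per_class lesions per class (>= 1). The default, 8, gives a
#'   32-lesion cohort.
#' @param geometry grid geometry shared by all phantoms.
#' @param class_params named list of per-class parameter ranges; see
#'   `default_class_params()` for the expected fields.
#' @param seed integer seed.
#' @param coverage_floor passed to [ground_truth()].
#' @return list with `phantoms` (list of [phantom_spec()]) and `truth`
#'   (truth table over the whole cohort, lesion_id in phantom order).
#' @export
generate_cohort <- function(n_per_class = 8L,
                            geometry = grid_geometry(),
                            class_params = default_class_params(),
                            seed = 1L,
                            coverage_floor = 0.25) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  set.seed(seed)
  phantoms <- list()
  jitter_mm <- 2  # keep lesions near the grid centre, away from wrap-around
  for (cls in names(class_params)) {
    p <- class_params[[cls]]
    for (i in seq_len(n_per_class)) {
      placed <- FALSE
      for (attempt in 1:50) {
        center <- stats::runif(3, -jitter_mm, jitter_mm)
        core_radius <- runif1(p$core_radius)
        core_chi <- runif1(p$core_chi)
        rim_chi <- runif1(p$rim_chi)
        rim_thickness <- runif1(p$rim_thickness)
        rim_coverage <- runif1(p$rim_coverage)
        rim_axis <- stats::rnorm(3); rim_axis <- rim_axis / sqrt(sum(rim_axis^2))
        vein <- NULL
        if (!is.null(p$vein_radius))
          vein <- list(axis = c(0, 0, 1), radius = runif1(p$vein_radius),
                       chi = p$vein_chi)
        les <- lesion_spec(center, core_radius, core_chi = core_chi,
                           rim_chi = rim_chi, rim_thickness = rim_thickness,
                           rim_coverage = rim_coverage, rim_axis = rim_axis,
                           vein = vein, class_label = cls)
        ph <- tryCatch(phantom_spec(geometry, list(les),
                                    seed = (seed + length(phantoms) * 131L) %% .Machine$integer.max),
                       error = function(e) NULL)
        if (!is.null(ph)) { phantoms[[length(phantoms) + 1L]] <- ph; placed <- TRUE; break }
      }
      if (!placed) stop(sprintf("could not place a '%s' lesion inside the grid", cls))
    }
  }
  truth <- ground_truth(phantoms, coverage_floor = coverage_floor)
  list(phantoms = phantoms, truth = truth)
}

#' Synthesize a multi-rater rim-call matrix
#'
#' Each rater's call on each lesion is an independent Bernoulli corruption of
#' the ground truth at that rater's sensitivity (probability of calling an
#' iron+ lesion rim+) and specificity (probability of calling an iron- lesion
#' rim-). Stands in for a panel of blinded readers.
#'
#' @param truth a truth table from [ground_truth()] (needs
#'   `iron_rim_status`).
#' @param sensitivity_per_rater,specificity_per_rater numeric vectors, one
#'   rate per rater, each in `[0, 1]` and of equal length.
#' @param seed integer seed.
#' @param session optional session identifier attached as an attribute.
#' @return character matrix `items x raters` of `"rim+"`/`"rim-"`, class
#'   `rating_matrix`, with rater ids as column names.
#' @export
generate_rating_matrix <- function(truth, sensitivity_per_rater,
                                   specificity_per_rater, seed = 1L,
                                   session = "s1") {
  if (length(sensitivity_per_rater) != length(specificity_per_rater))
    stop("sensitivity and specificity vectors must have one entry per rater")
  if (any(c(sensitivity_per_rater, specificity_per_rater) < 0) ||
      any(c(sensitivity_per_rater, specificity_per_rater) > 1))
    stop("rates must lie in [0, 1]")
  n_raters <- length(sensitivity_per_rater)
  is_pos <- truth$iron_rim_status == "iron+"
  set.seed(seed)
  m <- matrix(NA_character_, nrow = nrow(truth), ncol = n_raters,
              dimnames = list(NULL, paste0("rater", seq_len(n_raters))))
  for (r in seq_len(n_raters)) {
    u <- stats::runif(nrow(truth))
    call_pos <- ifelse(is_pos, u <= sensitivity_per_rater[r],
                               u >  specificity_per_rater[r])
    m[, r] <- ifelse(call_pos, "rim+", "rim-")
  }
  attr(m, "session") <- session
  class(m) <- c("rating_matrix", class(m))
  m
}
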