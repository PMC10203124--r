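# Grid and holey-film geometry.
#
# A support grid is a metal mesh (200/300/400 squares per inch) carrying a
# thin film, usually perforated by a square lattice of circular holes.
# Conventions: lengths in micrometres, power densities in W/cm^2.

#' Describe a holey support-film pattern
#'
#' A holey film is specified by its hole diameter and the edge-to-edge gap
#' between adjacent holes, following the supplier "d/s" shorthand (a "2/1"
#' film has 2 um holes separated by 1 um of material). Holes are assumed to
#' sit on a square lattice with pitch `hole_diameter + hole_spacing`;
#' `lattice = "none"` describes a continuous (unperforated) film.
#'
#' @param hole_diameter Hole diameter in um. Ignored for continuous films.
#' @param hole_spacing Edge-to-edge spacing between adjacent holes in um.
#' @param lattice `"square"` for a square hole lattice, `"none"` for a
#'   continuous film.
#' @return An object of class `holey_film`.
#' @examples
#' holey_film(2, 1)              # "2/1" holey film, 65% carbon
#' holey_film(lattice = "none")  # continuous film
#' @export
holey_film <- function(hole_diameter = NULL, hole_spacing = NULL,
                       lattice = c("square", "none")) {
  lattice <- match.arg(lattice)
  if (lattice == "none") {
    out <- list(hole_diameter = NA_real_, hole_spacing = NA_real_,
                lattice = "none")
    class(out) <- "holey_film"
    return(out)
  }
  if (is.null(hole_diameter) || is.null(hole_spacing))
    stop("square-lattice films need both `hole_diameter` and `hole_spacing`")
  hole_diameter <- as.numeric(hole_diameter)
  hole_spacing <- as.numeric(hole_spacing)
  if (!is.finite(hole_diameter) || hole_diameter <= 0)
    stop("`hole_diameter` must be positive")
  if (!is.finite(hole_spacing) || hole_spacing < 0)
    stop("invalid geometry: `hole_spacing` must be non-negative ",
         "(negative spacing means overlapping holes)")
  out <- list(hole_diameter = hole_diameter, hole_spacing = hole_spacing,
              lattice = "square")
  class(out) <- "holey_film"
  out
}

#' @export
print.holey_film <- function(x, ...) {
  if (x$lattice == "none") {
    cat("<holey_film> continuous film\n")
  } else {
    cat(sprintf("<holey_film> %g/%g square lattice (%.1f%% material)\n",
                x$hole_diameter, x$hole_spacing,
                100 * carbon_area_fraction(x)))
  }
  invisible(x)
}

#' Carbon (material) area fraction of a holey film
#'
#' Fraction of the film plane covered by material rather than holes,
#' `eta_c`. For circular holes of diameter d on a square lattice with pitch
#' d + s this is `1 - pi (d/2)^2 / (d + s)^2`; a continuous film has
#' `eta_c = 1`. The material fraction scales the light absorbed (and hence
#' the heat generated) per unit illuminated area.
#'
#' @param pattern A [holey_film()] object.
#' @return Material area fraction in (0, 1].
#' @examples
#' carbon_area_fraction(holey_film(2, 1))      # ~0.651 -> "65% carbon"
#' carbon_area_fraction(holey_film(1, 4))      # ~0.969 -> "97% carbon"
#' carbon_area_fraction(holey_film(1.2, 1.3))  # ~0.819 -> "82% carbon"
#' @export
carbon_area_fraction <- function(pattern) {
  stopifnot(inherits(pattern, "holey_film"))
  if (pattern$lattice == "none") return(1)
  d <- pattern$hole_diameter
  pitch <- d + pattern$hole_spacing
  # holes on a square lattice overlap their nearest neighbours when d > pitch
  if (d > pitch)
    stop("invalid geometry: holes overlap (diameter exceeds lattice pitch)")
  1 - pi * (d / 2)^2 / pitch^2
}

# Printed grid-square sizes for the standard meshes. These are measured
# values; the implied bar width is not constant across meshes, so the lookup
# takes precedence over the pitch-minus-bar formula.
.mesh_square_lookup <- c("200" = 90, "300" = 58, "400" = 37)

# Bar width consistent with the 300- and 400-mesh square sizes
# (25400/300 - 58 = 26.2, 25400/400 - 37 = 26.5).
.default_bar_width_um <- 26.5

#' Grid-square size from mesh number
#'
#' Converts a mesh count (grid squares per inch) to the open square size L
#' in um. For the standard meshes 200/300/400 the measured square sizes
#' (90, 58 and 37 um) are returned directly; for other meshes the square
#' size is the mesh pitch 25400/mesh minus the bar width.
#'
#' @param mesh Squares per inch (> 0).
#' @param bar_width Grid-bar width in um. When supplied, the formula
#'   `25400/mesh - bar_width` is always used; when absent, standard meshes
#'   use the measured lookup and other meshes assume a 26.5 um bar.
#' @return Square size L in um.
#' @examples
#' square_size_from_mesh(300)  # 58
#' square_size_from_mesh(508, bar_width = 25)  # 25
#' @export
square_size_from_mesh <- function(mesh, bar_width = NULL) {
  stopifnot(is.numeric(mesh), length(mesh) == 1, mesh > 0)
  key <- as.character(mesh)
  if (is.null(bar_width) && key %in% names(.mesh_square_lookup))
    return(unname(.mesh_square_lookup[key]))
  if (is.null(bar_width)) bar_width <- .default_bar_width_um
  L <- 25400 / mesh - bar_width
  if (L <= 0)
    stop("invalid geometry: bar width leaves no open square at mesh ", mesh)
  L
}

#' Describe a support grid
#'
#' Bundles everything the thermal model needs to know about a grid: the film
#' material (a key into the calibration), the holey-film pattern, and the
#' grid-square size (given directly or derived from the mesh). The bar metal
#' is carried for bookkeeping: the model treats the bars as ideal isothermal
#' heat sinks, so the metal never enters a prediction.
#'
#' @param grid_id Identifier for the grid.
#' @param film_material Material key, e.g. `"carbon_cflat"`,
#'   `"carbon_quantifoil"`, `"gold_film"`, `"formvar"`, `"silicon_monoxide"`.
#' @param film_pattern A [holey_film()] object.
#' @param mesh Squares per inch (optional if `square_size` is given).
#' @param square_size Grid-square size L in um (optional if `mesh` is given).
#' @param bar_metal `"copper"`, `"gold"` or `"nickel"`.
#' @param film_thickness Film thickness in nm; informational only, the
#'   calibrated film parameter absorbs it.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec("CF312", "carbon_cflat", holey_film(2, 1), mesh = 300)
#' @export
grid_spec <- function(grid_id, film_material, film_pattern,
                      mesh = NULL, square_size = NULL,
                      bar_metal = c("copper", "gold", "nickel"),
                      film_thickness = NULL) {
  bar_metal <- match.arg(bar_metal)
  stopifnot(inherits(film_pattern, "holey_film"))
  if (is.null(square_size)) {
    if (is.null(mesh)) stop("give either `mesh` or `square_size`")
    square_size <- square_size_from_mesh(mesh)
  }
  stopifnot(square_size > 0)
  if (!is.null(mesh) && square_size >= 25400 / mesh)
    stop("invalid geometry: square size ", square_size,
         " um exceeds the mesh pitch ", signif(25400 / mesh, 4), " um")
  out <- list(grid_id = as.character(grid_id),
              film_material = as.character(film_material),
              film_pattern = film_pattern,
              mesh = mesh,
              square_size = square_size,
              bar_metal = bar_metal,
              film_thickness = film_thickness)
  class(out) <- "grid_spec"
  out
}

#' @export
print.grid_spec <- function(x, ...) {
  pat <- if (x$film_pattern$lattice == "none") "continuous" else
    sprintf("%g/%g", x$film_pattern$hole_diameter, x$film_pattern$hole_spacing)
  cat(sprintf("<grid_spec> %s: %s %s film, L = %g um, %s bars\n",
              x$grid_id, x$film_material, pat, x$square_size, x$bar_metal))
  invisible(x)
}

#' Rasterize the film absorption mask over one grid square
#'
#' Builds a binary raster over the L x L grid square: 1 where film material
#' is present, 0 inside a hole. The hole lattice is phase-centred on the
#' square centre; pixel centres sit at `(i - 0.5)/resolution` um from the
#' square corner. The raster mean converges to [carbon_area_fraction()] as
#' the resolution grows, and multiplied with an illumination intensity map
#' it forms the heat source of the 2D solver.
#'
#' @param x A [grid_spec()] or [holey_film()] object.
#' @param resolution Pixels per um; must give at least 32 pixels across L.
#' @param L Square size in um (required when `x` is a bare pattern).
#' @return A numeric 0/1 matrix (rows = y, columns = x).
#' @export
film_mask <- function(x, resolution, L = NULL) {
  if (inherits(x, "grid_spec")) {
    pattern <- x$film_pattern
    L <- x$square_size
  } else if (inherits(x, "holey_film")) {
    if (is.null(L)) stop("`L` is required when `x` is a holey_film pattern")
    pattern <- x
  } else stop("`x` must be a grid_spec or holey_film")
  n <- round(L * resolution)
  if (n < 32)
    stop("resolution too coarse: need >= 32 pixels across the square, got ", n)
  if (pattern$lattice == "none")
    return(matrix(1, n, n))
  carbon_area_fraction(pattern)  # validates hole geometry
  pitch <- pattern$hole_diameter + pattern$hole_spacing
  r2 <- (pattern$hole_diameter / 2)^2
  coords <- ((seq_len(n) - 0.5) / resolution) - L / 2
  # signed distance to the nearest lattice line of hole centres
  dmin <- function(u) {
    m <- u %% pitch
    pmin(m, pitch - m)
  }
  dx <- dmin(coords)
  dy <- dmin(coords)
  inside_hole <- outer(dy^2, dx^2, "+") < r2
  mask <- matrix(1, n, n)
  mask[inside_hole] <- 0
  mask
}

#' Read a grid catalogue with threshold measurements
#'
#' Reads a CSV catalogue of grids (one row per grid) with the columns
#' `grid_id, supplier_name, film_material, hole_diameter_um, hole_spacing_um,
#' mesh, square_size_um, bar_metal, measured_pmax_W_cm2, censor`. The
#' `censor` column is `"none"` for an observed threshold, `"gt"` for a
#' lower bound (the instrument ceiling was reached without damage) and
#' `"lt"` for an upper bound. Missing hole columns denote a continuous film.
#' A derived `eta_c` column (material area fraction) is appended.
#'
#' @param path Path to the CSV file; defaults to the packaged measurement
#'   table of maximum illumination power densities.
#' @return A data frame, one row per grid.
#' @export
read_grid_catalogue <- function(path = table1_path()) {
  cat_df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("grid_id", "film_material", "hole_diameter_um",
                "hole_spacing_um", "mesh", "square_size_um", "bar_metal",
                "measured_pmax_W_cm2", "censor")
  missing <- setdiff(required, names(cat_df))
  if (length(missing))
    stop("catalogue is missing columns: ", paste(missing, collapse = ", "))
  bad <- !cat_df$censor %in% c("none", "gt", "lt")
  if (any(bad))
    stop("unknown censor codes: ", paste(unique(cat_df$censor[bad]), collapse = ", "))
  cat_df$eta_c <- vapply(seq_len(nrow(cat_df)), function(i) {
    carbon_area_fraction(catalogue_pattern(cat_df[i, ]))
  }, numeric(1))
  cat_df
}

#' Path to the packaged maximum-illumination measurement table
#'
#' The packaged fixture holds the measured maximum illumination power
#' densities (488 nm) for the surveyed commercial grids, including the
#' censored formvar/silicon-monoxide rows where the 690 W/cm^2 instrument
#' ceiling was reached without damage.
#'
#' @return Path to the CSV file.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.csv", package = "gridheat", mustWork = TRUE)
}

# Build a holey_film from one catalogue row.
catalogue_pattern <- function(row) {
  d <- row$hole_diameter_um
  s <- row$hole_spacing_um
  if (is.na(d) || is.na(s)) holey_film(lattice = "none") else holey_film(d, s)
}

# Build a grid_spec from one catalogue row.
catalogue_spec <- function(row) {
  grid_spec(row$grid_id, row$film_material, catalogue_pattern(row),
            mesh = row$mesh, square_size = row$square_size_um,
            bar_metal = row$bar_metal)
}
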