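#' Maxilloturbinate geometry profile
#'
#' Constructs a discretized geometry of the maxilloturbinate (MT) airway:
#' per-slice cross-sectional area available for airflow `Aa` (m^2) and the
#' air--tissue perimeter `gamma_a` (m) as functions of the scaled axial
#' position `z_star = z / L` in `[0, 1]`.
#'
#' @param z_star numeric, strictly increasing scaled positions; first >= 0,
#'   last <= 1.
#' @param Aa numeric, airflow cross-sectional area per node, m^2 (> 0).
#' @param gamma_a numeric, air--tissue perimeter per node, m (> 0).
#' @param L MT length in m (> 0).
#' @param label free-text provenance (species/case).
#' @return An object of class `mt_geometry`: a list with fields `z_star`,
#'   `Aa`, `gamma_a`, `L`, `label`.
#' @seealso [load_geometry()], [synth_geometry()], [perturb()], [complexity()]
#' @export
mt_geometry <- function(z_star, Aa, gamma_a, L, label = "unlabelled") {
  z_star <- as.numeric(z_star)
  Aa <- as.numeric(Aa)
  gamma_a <- as.numeric(gamma_a)
  n <- length(z_star)
  if (n < 4L)
    stop("mt_geometry needs at least 4 nodes, got ", n)
  if (length(Aa) != n || length(gamma_a) != n)
    stop("z_star, Aa and gamma_a must have equal length")
  if (anyNA(z_star) || anyNA(Aa) || anyNA(gamma_a))
    stop("geometry profiles contain missing values")
  if (any(diff(z_star) <= 0))
    stop("non-monotonic z_star: positions must be strictly increasing")
  if (z_star[1] < 0 || z_star[n] > 1)
    stop("z_star must lie within [0, 1]")
  bad <- which(Aa <= 0 | gamma_a <= 0)
  if (length(bad) > 0)
    stop("non-positive Aa or gamma_a at row ", bad[1])
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("L must be a positive length in m")
  structure(
    list(z_star = z_star, Aa = Aa, gamma_a = gamma_a, L = as.numeric(L),
         label = as.character(label)),
    class = "mt_geometry")
}

#' @export
print.mt_geometry <- function(x, ...) {
  cat("MT geometry:", x$label, "\n")
  cat(sprintf("  %d nodes on z* in [%.3f, %.3f], L = %.4g m\n",
              length(x$z_star), x$z_star[1], x$z_star[length(x$z_star)], x$L))
  cat(sprintf("  max Aa      = %.4g m^2\n", max(x$Aa)))
  cat(sprintf("  max gamma_a = %.4g m\n", max(x$gamma_a)))
  cat(sprintf("  complexity gamma_a/Aa in [%.0f, %.0f] 1/m\n",
              min(complexity(x)), max(complexity(x))))
  invisible(x)
}

#' Load an MT geometry profile table
#'
#' Reads a delimited text table (comma or tab separated, one header line)
#' with columns `z_star`, `Aa_m2`, `gamma_m` -- one row per CT slice.
#'
#' @param path path to the profile table.
#' @param L MT length in m.
#' @param label provenance label; defaults to the file name.
#' @return an [mt_geometry()] with nodes sorted by `z_star`.
#' @export
load_geometry <- function(path, L, label = basename(path)) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           strip.white = TRUE, stringsAsFactors = FALSE)
  need <- c("z_star", "Aa_m2", "gamma_m")
  if (!all(need %in% names(tab)))
    stop("geometry table must have columns ", paste(need, collapse = ", "),
         "; found ", paste(names(tab), collapse = ", "))
  if (nrow(tab) < 4L)
    stop("geometry table needs at least 4 rows")
  for (cn in need)
    if (!is.numeric(tab[[cn]]))
      stop("column ", cn, " is not numeric")
  ord <- order(tab$z_star)
  tab <- tab[ord, , drop = FALSE]
  if (any(diff(tab$z_star) <= 0))
    stop("non-monotonic z_star: duplicated positions in geometry table")
  mt_geometry(tab$z_star, tab$Aa_m2, tab$gamma_m, L = L, label = label)
}

#' Write an MT geometry profile table
#'
#' Inverse of [load_geometry()]: writes the comma-delimited profile table
#' with header `z_star,Aa_m2,gamma_m`.
#'
#' @param geom an [mt_geometry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "mt_geometry"))
  tab <- data.frame(z_star = geom$z_star, Aa_m2 = geom$Aa,
                    gamma_m = geom$gamma_a)
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Synthetic single-humped MT geometry
#'
#' Generates smooth, deterministic area and perimeter profiles emulating the
#' measured CT morphometry of a seal MT: single-humped curves supported on
#' `[z_lo, z_hi]`, peaking at the midpoint with the stated maxima and falling
#' to `edge_fraction` times the peak at the support endpoints. The hump is a
#' raised-cosine bell, which reproduces the qualitative single-peak shape of
#' the measured profiles with two parameters.
#'
#' @param Aa_max peak airflow cross-sectional area, m^2.
#' @param gamma_max peak air--tissue perimeter, m.
#' @param z_lo,z_hi support range on the scaled axis, `0 <= z_lo < z_hi <= 1`.
#' @param n_nodes number of nodes (>= 4).
#' @param L MT length, m.
#' @param edge_fraction endpoint value as a fraction of the peak, in (0, 1].
#' @param label provenance label.
#' @return an [mt_geometry()].
#' @export
synth_geometry <- function(Aa_max, gamma_max, z_lo, z_hi, n_nodes, L,
                           edge_fraction = 0.2, label = "synthetic") {
  if (!(z_lo >= 0 && z_lo < z_hi && z_hi <= 1))
    stop("degenerate support: need 0 <= z_lo < z_hi <= 1")
  if (n_nodes < 4L) stop("n_nodes must be >= 4")
  if (!(edge_fraction > 0 && edge_fraction <= 1))
    stop("edge_fraction must be in (0, 1]")
  if (Aa_max <= 0 || gamma_max <= 0) stop("peak values must be positive")
  z <- seq(z_lo, z_hi, length.out = n_nodes)
  s <- (z - z_lo) / (z_hi - z_lo)
  bell <- 0.5 * (1 - cos(2 * pi * s))   # 0 at ends, 1 at midpoint
  shape <- edge_fraction + (1 - edge_fraction) * bell
  mt_geometry(z, Aa_max * shape, gamma_max * shape, L = L, label = label)
}

#' Geometry perturbation for the sensitivity case studies
#'
#' The sensitivity cases scale the profiles node-wise: `A0` is the unmodified
#' reference, `A1` multiplies the area `Aa` by 1.2^2 = 1.44, `A2` multiplies
#' the perimeter `gamma_a` by 1.2, and `A3` applies both.
#'
#' @param case_id one of `"A0"`, `"A1"`, `"A2"`, `"A3"`.
#' @return an object of class `case_perturbation` with fields `case_id`,
#'   `area_factor`, `perim_factor`.
#' @export
case_perturbation <- function(case_id = c("A0", "A1", "A2", "A3")) {
  case_id <- match.arg(case_id)
  area_factor <- switch(case_id, A0 = 1, A1 = 1.2^2, A2 = 1, A3 = 1.2^2)
  perim_factor <- switch(case_id, A0 = 1, A1 = 1, A2 = 1.2, A3 = 1.2)
  structure(list(case_id = case_id, area_factor = area_factor,
                 perim_factor = perim_factor),
            class = "case_perturbation")
}

#' Apply a geometry perturbation
#'
#' @param geom an [mt_geometry()].
#' @param pert a [case_perturbation()] or a case id string.
#' @return the perturbed [mt_geometry()].
#' @export
perturb <- function(geom, pert) {
  stopifnot(inherits(geom, "mt_geometry"))
  if (is.character(pert)) pert <- case_perturbation(pert)
  stopifnot(inherits(pert, "case_perturbation"))
  if (pert$area_factor <= 0 || pert$perim_factor <= 0)
    stop("perturbation factors must be positive")
  mt_geometry(geom$z_star, geom$Aa * pert$area_factor,
              geom$gamma_a * pert$perim_factor, L = geom$L,
              label = paste0(geom$label, " [", pert$case_id, "]"))
}

#' Complexity factor of the turbinate cross section
#'
#' The perimeter-to-area ratio `gamma_a / Aa` (units 1/m as used here), a
#' proxy for the elaboration of the turbinate scrolls: more perimeter per
#' unit airflow area means more exchange surface per unit of transported air.
#'
#' @param geom an [mt_geometry()].
#' @return numeric vector, the per-node complexity profile, 1/m.
#' @export
complexity <- function(geom) {
  stopifnot(inherits(geom, "mt_geometry"))
  geom$gamma_a / geom$Aa
}

#' Interpolate a geometry onto a uniform solver grid
#'
#' Monotone piecewise-cubic (Fritsch--Carlson) interpolation of `Aa` and
#' `gamma_a` versus `z_star` onto `Ns` uniformly spaced nodes spanning the
#' geometry's support. Monotone interpolation cannot overshoot below zero
#' between positive data points.
#'
#' @param geom an [mt_geometry()].
#' @param Ns number of grid nodes (>= 6).
#' @return a list with `z_star`, `z` (m), `dz` (m), `Aa`, `gamma_a`, `L`.
#' @export
geometry_on_grid <- function(geom, Ns) {
  stopifnot(inherits(geom, "mt_geometry"))
  if (Ns < 6L) stop("solver grid needs Ns >= 6")
  zs <- seq(geom$z_star[1], geom$z_star[length(geom$z_star)],
            length.out = Ns)
  f_A <- stats::splinefun(geom$z_star, geom$Aa, method = "monoH.FC")
  f_g <- stats::splinefun(geom$z_star, geom$gamma_a, method = "monoH.FC")
  Aa <- f_A(zs)
  ga <- f_g(zs)
  # monotone interpolation between positive data stays positive
  stopifnot(all(Aa > 0), all(ga > 0))
  list(z_star = zs, z = zs * geom$L, dz = (zs[2] - zs[1]) * geom$L,
       Aa = Aa, gamma_a = ga, L = geom$L)
}
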