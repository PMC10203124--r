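# Calibration of the effective film parameter and the grid-selection
# analyses.
#
# The thermal model has one free parameter per film material: alpha, the
# lumped absorptivity-over-conductance. It is identified by inverting the
# closed-form threshold relation P_max = 8 (Tmax - T0) / (alpha eta_c L^2)
# on measured thresholds. Measurements span more than a 40-fold range, so
# the fit minimises squared residuals on the log scale (a multiplicative
# error model). Censored measurements — thresholds beyond the instrument
# ceiling ("gt") or only known to lie below a value ("lt") — never enter
# the point fit; they carry bounds on alpha and are checked for
# consistency against the fitted value.

delta_T <- function(params) params$Tmax - params$T0

# alpha implied by a single (eta_c, L, P_max) observation.
alpha_from_row <- function(eta_c, L, pmax, params) {
  8 * delta_T(params) / (eta_c * L^2 * pmax)
}

#' Fit the effective film parameter per material
#'
#' Inverts the closed-form threshold relation on every uncensored
#' measurement and takes the geometric mean per material (equivalently, the
#' least-squares fit of log alpha to the log thresholds). Censored rows
#' yield bounds: a `"gt"` row (true threshold above the recorded ceiling)
#' bounds alpha from above, a `"lt"` row bounds it from below. Materials
#' with only censored rows get a bound-only result with `alpha = NA`.
#'
#' @param measurements Data frame of threshold measurements with columns
#'   `grid_id`, `measured_pmax_W_cm2`, `censor`; geometry columns
#'   (`film_material`, `square_size_um`, `eta_c` or the hole columns) may be
#'   present directly or supplied via `catalogue`.
#' @param catalogue Optional grid catalogue (as from
#'   [read_grid_catalogue()]) merged onto `measurements` by `grid_id`.
#' @param params A [thermal_params()]; `alpha_eff` is ignored.
#' @return A `calibration_result`: list with `materials` (per-material
#'   estimates and bounds), `residuals` (per uncensored measurement, log
#'   scale) and `flags` (censored rows inconsistent with the fit).
#' @examples
#' cal <- fit_alpha(read_grid_catalogue())
#' cal$materials
#' @export
fit_alpha <- function(measurements, catalogue = NULL,
                      params = thermal_params()) {
  stopifnot(is.data.frame(measurements))
  if (!is.null(catalogue)) {
    geom_cols <- setdiff(names(catalogue), names(measurements))
    measurements <- merge(measurements,
                          catalogue[, c("grid_id", geom_cols)],
                          by = "grid_id", sort = FALSE)
  }
  if (!"eta_c" %in% names(measurements)) {
    measurements$eta_c <- vapply(seq_len(nrow(measurements)), function(i)
      carbon_area_fraction(catalogue_pattern(measurements[i, ])), numeric(1))
  }
  needed <- c("grid_id", "film_material", "square_size_um", "eta_c",
              "measured_pmax_W_cm2", "censor")
  missing <- setdiff(needed, names(measurements))
  if (length(missing))
    stop("measurements lack columns: ", paste(missing, collapse = ", "))

  mats <- unique(measurements$film_material)
  mat_rows <- list(); resid_rows <- list(); flag_rows <- list()
  for (m in mats) {
    rows <- measurements[measurements$film_material == m, ]
    unc <- rows[rows$censor == "none", ]
    gt <- rows[rows$censor == "gt", ]
    lt <- rows[rows$censor == "lt", ]
    a_i <- alpha_from_row(unc$eta_c, unc$square_size_um,
                          unc$measured_pmax_W_cm2, params)
    alpha_hat <- if (nrow(unc)) exp(mean(log(a_i))) else NA_real_
    # bounds implied by censored rows
    alpha_upper <- if (nrow(gt))
      min(alpha_from_row(gt$eta_c, gt$square_size_um,
                         gt$measured_pmax_W_cm2, params)) else NA_real_
    alpha_lower <- if (nrow(lt))
      max(alpha_from_row(lt$eta_c, lt$square_size_um,
                         lt$measured_pmax_W_cm2, params)) else NA_real_
    resid_sd <- NA_real_
    if (nrow(unc)) {
      pred <- 8 * delta_T(params) /
        (alpha_hat * unc$eta_c * unc$square_size_um^2)
      lr <- log(unc$measured_pmax_W_cm2) - log(pred)
      resid_sd <- if (nrow(unc) > 1) stats::sd(lr) else 0
      resid_rows[[m]] <- data.frame(
        grid_id = unc$grid_id, film_material = m,
        observed_pmax = unc$measured_pmax_W_cm2, predicted_pmax = pred,
        log_residual = lr, stringsAsFactors = FALSE)
      # consistency of censored rows with the fitted alpha
      for (j in seq_len(nrow(gt))) {
        pred_j <- 8 * delta_T(params) /
          (alpha_hat * gt$eta_c[j] * gt$square_size_um[j]^2)
        flag_rows[[paste(m, gt$grid_id[j])]] <- data.frame(
          grid_id = gt$grid_id[j], film_material = m, censor = "gt",
          bound_pmax = gt$measured_pmax_W_cm2[j], predicted_pmax = pred_j,
          consistent = pred_j > gt$measured_pmax_W_cm2[j],
          stringsAsFactors = FALSE)
      }
      for (j in seq_len(nrow(lt))) {
        pred_j <- 8 * delta_T(params) /
          (alpha_hat * lt$eta_c[j] * lt$square_size_um[j]^2)
        flag_rows[[paste(m, lt$grid_id[j])]] <- data.frame(
          grid_id = lt$grid_id[j], film_material = m, censor = "lt",
          bound_pmax = lt$measured_pmax_W_cm2[j], predicted_pmax = pred_j,
          consistent = pred_j < lt$measured_pmax_W_cm2[j],
          stringsAsFactors = FALSE)
      }
    }
    mat_rows[[m]] <- data.frame(
      film_material = m, alpha = alpha_hat, alpha_lower = alpha_lower,
      alpha_upper = alpha_upper, n_uncensored = nrow(unc),
      n_censored = nrow(gt) + nrow(lt), resid_sd_log = resid_sd,
      stringsAsFactors = FALSE)
  }
  out <- list(
    materials = do.call(rbind, c(mat_rows, make.row.names = FALSE)),
    residuals = if (length(resid_rows))
      do.call(rbind, c(resid_rows, make.row.names = FALSE)) else NULL,
    flags = if (length(flag_rows))
      do.call(rbind, c(flag_rows, make.row.names = FALSE)) else NULL,
    params = params)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  print(x$materials, row.names = FALSE)
  if (!is.null(x$flags) && any(!x$flags$consistent))
    cat("warning:", sum(!x$flags$consistent),
        "censored row(s) inconsistent with the fit\n")
  invisible(x)
}

#' Predict the damage threshold for a grid design
#'
#' Applies the closed-form threshold relation with the calibrated alpha of
#' the grid's film material. The bar metal never enters: both copper and
#' gold bars are treated as ideal isothermal sinks, so predictions are
#' identical across bar metals. For materials known only through censored
#' measurements the prediction is a bound: an upper bound on alpha gives a
#' lower bound on the threshold ("at least this much").
#'
#' @param spec A [grid_spec()].
#' @param calibration A `calibration_result` from [fit_alpha()].
#' @param params A [thermal_params()]; defaults to the calibration's.
#' @return List with `grid_id`, `pmax` (W/cm^2) and `bound` (`"none"`,
#'   `"lower"` or `"upper"`).
#' @export
predict_threshold <- function(spec, calibration, params = calibration$params) {
  stopifnot(inherits(spec, "grid_spec"),
            inherits(calibration, "calibration_result"))
  row <- calibration$materials[
    calibration$materials$film_material == spec$film_material, ]
  if (nrow(row) != 1)
    stop("material `", spec$film_material, "` is not calibrated; available: ",
         paste(calibration$materials$film_material, collapse = ", "))
  eta <- carbon_area_fraction(spec$film_pattern)
  pm <- function(a) max_power_density(a, spec$square_size, params$T0,
                                      params$Tmax, eta)
  if (!is.na(row$alpha)) {
    return(list(grid_id = spec$grid_id, pmax = pm(row$alpha),
                bound = "none"))
  }
  if (!is.na(row$alpha_upper)) {
    # alpha below its upper bound => threshold above the implied value
    return(list(grid_id = spec$grid_id, pmax = pm(row$alpha_upper),
                bound = "lower"))
  }
  if (!is.na(row$alpha_lower)) {
    return(list(grid_id = spec$grid_id, pmax = pm(row$alpha_lower),
                bound = "upper"))
  }
  stop("material `", spec$film_material, "` carries no estimate or bound")
}

#' Carbon-fraction scaling-law check
#'
#' At fixed material and mesh the model predicts `eta_c * P_max = constant`:
#' the absorbed (not incident) power density sets the temperature. Given
#' two (eta_c, P_max) pairs this returns the relative difference of the two
#' products in percent, with the larger product as denominator.
#'
#' @param pair1,pair2 Numeric length-2 vectors `c(eta_c, P_max)`.
#' @param censor1,censor2 Censor codes of the two measurements; anything
#'   other than `"none"` is an error, since a censored threshold has no
#'   defined product.
#' @return Relative difference of `eta_c * P_max` in percent.
#' @examples
#' eta <- carbon_area_fraction(holey_film(2, 1))
#' eta2 <- carbon_area_fraction(holey_film(1.2, 1.3))
#' scaling_law_check(c(eta, 64), c(eta2, 50))  # ~1.7%
#' @export
scaling_law_check <- function(pair1, pair2, censor1 = "none",
                              censor2 = "none") {
  if (censor1 != "none" || censor2 != "none")
    stop("scaling-law check requires uncensored thresholds")
  stopifnot(length(pair1) == 2, length(pair2) == 2,
            all(is.finite(c(pair1, pair2))), all(c(pair1, pair2) > 0))
  p1 <- pair1[1] * pair1[2]
  p2 <- pair2[1] * pair2[2]
  100 * abs(p1 - p2) / max(p1, p2)
}

# Locate a catalogue row by material, pattern ("d/s" string or "continuous")
# and mesh; error naming the row if absent.
find_row <- function(cat_df, material, pattern, mesh, bar_metal = NULL) {
  pat_str <- ifelse(is.na(cat_df$hole_diameter_um), "continuous",
                    paste0(cat_df$hole_diameter_um, "/",
                           cat_df$hole_spacing_um))
  sel <- cat_df$film_material == material & pat_str == pattern &
    cat_df$mesh == mesh
  if (!is.null(bar_metal)) sel <- sel & cat_df$bar_metal == bar_metal
  if (sum(sel) != 1)
    stop("catalogue row not found (or ambiguous): ", material, " ", pattern,
         " ", mesh, " mesh", if (!is.null(bar_metal)) paste0(" ", bar_metal))
  cat_df[sel, ]
}

#' Grid-comparison report
#'
#' Reproduces the four grid-selection comparisons from a measurement
#' catalogue:
#' \describe{
#'   \item{mesh_series}{2/1 CFlat carbon across 200/300/400 mesh: measured
#'     threshold ratios of consecutive meshes against the model's `1/L^2`
#'     prediction, with the deviation in percent. The model is qualitative;
#'     the deviation quantifies how far the measured mesh effect falls
#'     short of the ideal-sink scaling.}
#'   \item{metal_pair}{identical CFlat 1.2/1.3 300-mesh films on copper vs
#'     gold bars: threshold ratio (1 if both metals sink heat ideally).}
#'   \item{manufacturing}{Quantifoil vs CFlat 2/1 200-mesh threshold ratio
#'     in percent: the two makes differ in film thickness/absorptivity.}
#'   \item{scaling_checks}{`eta_c * P_max` conservation for the CFlat
#'     (2/1 vs 1.2/1.3, 300 mesh) and Quantifoil (2/1 vs 1/4, 200 mesh)
#'     film-geometry pairs.}
#' }
#'
#' @param cat_df Catalogue data frame from [read_grid_catalogue()].
#' @return A list of class `comparison_report`.
#' @export
comparison_report <- function(cat_df = read_grid_catalogue()) {
  stopifnot(is.data.frame(cat_df))
  # (a) mesh series
  meshes <- c(200, 300, 400)
  series <- do.call(rbind, lapply(meshes, function(m)
    find_row(cat_df, "carbon_cflat", "2/1", m)))
  mesh_pairs <- data.frame(
    mesh_from = meshes[-3], mesh_to = meshes[-1],
    L_from = series$square_size_um[-3], L_to = series$square_size_um[-1],
    measured_ratio = series$measured_pmax_W_cm2[-1] /
      series$measured_pmax_W_cm2[-3],
    model_ratio = (series$square_size_um[-3] / series$square_size_um[-1])^2)
  mesh_pairs$deviation_percent <-
    100 * (mesh_pairs$model_ratio - mesh_pairs$measured_ratio) /
    mesh_pairs$model_ratio
  # (b) metal pair
  cu <- find_row(cat_df, "carbon_cflat", "1.2/1.3", 300, "copper")
  au <- find_row(cat_df, "carbon_cflat", "1.2/1.3", 300, "gold")
  metal_pair <- list(copper_pmax = cu$measured_pmax_W_cm2,
                     gold_pmax = au$measured_pmax_W_cm2,
                     ratio = cu$measured_pmax_W_cm2 / au$measured_pmax_W_cm2)
  # (c) manufacturing
  qf <- find_row(cat_df, "carbon_quantifoil", "2/1", 200)
  cf <- find_row(cat_df, "carbon_cflat", "2/1", 200)
  manufacturing <- list(
    quantifoil_pmax = qf$measured_pmax_W_cm2,
    cflat_pmax = cf$measured_pmax_W_cm2,
    ratio_percent = 100 * qf$measured_pmax_W_cm2 / cf$measured_pmax_W_cm2)
  # (d) film-geometry scaling law
  cf21 <- find_row(cat_df, "carbon_cflat", "2/1", 300)
  cf1213 <- find_row(cat_df, "carbon_cflat", "1.2/1.3", 300, "copper")
  qf21 <- find_row(cat_df, "carbon_quantifoil", "2/1", 200)
  qf14 <- find_row(cat_df, "carbon_quantifoil", "1/4", 200)
  scaling_checks <- data.frame(
    set = c("cflat_300mesh", "quantifoil_200mesh"),
    pattern_1 = c("2/1", "2/1"), pattern_2 = c("1.2/1.3", "1/4"),
    product_1 = c(cf21$eta_c * cf21$measured_pmax_W_cm2,
                  qf21$eta_c * qf21$measured_pmax_W_cm2),
    product_2 = c(cf1213$eta_c * cf1213$measured_pmax_W_cm2,
                  qf14$eta_c * qf14$measured_pmax_W_cm2),
    rel_diff_percent = c(
      scaling_law_check(c(cf21$eta_c, cf21$measured_pmax_W_cm2),
                        c(cf1213$eta_c, cf1213$measured_pmax_W_cm2)),
      scaling_law_check(c(qf21$eta_c, qf21$measured_pmax_W_cm2),
                        c(qf14$eta_c, qf14$measured_pmax_W_cm2))),
    stringsAsFactors = FALSE)
  out <- list(mesh_series = mesh_pairs, metal_pair = metal_pair,
              manufacturing = manufacturing, scaling_checks = scaling_checks)
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n\nMesh series (2/1 CFlat carbon):\n")
  print(x$mesh_series, row.names = FALSE)
  cat(sprintf("\nBar metal (CFlat 1.2/1.3, 300 mesh): Cu %g vs Au %g W/cm^2 (ratio %.2f)\n",
              x$metal_pair$copper_pmax, x$metal_pair$gold_pmax,
              x$metal_pair$ratio))
  cat(sprintf("Manufacturing (2/1, 200 mesh): Quantifoil damages at %.0f%% of the CFlat threshold\n",
              x$manufacturing$ratio_percent))
  cat("\nFilm-geometry scaling (eta_c * P_max conservation):\n")
  print(x$scaling_checks, row.names = FALSE)
  invisible(x)
}

#' Rank grid designs by predicted damage threshold
#'
#' Predicts the threshold for every catalogue row from the calibration and
#' orders designs by predicted `P_max`, descending. Ties break by lower
#' material fraction, then smaller square, then `grid_id`, so the ordering
#' is deterministic. Each design is flagged usable if the required imaging
#' power stays within the 70% operating margin of its predicted threshold.
#'
#' @param cat_df Catalogue data frame (geometry columns required;
#'   measurements ignored).
#' @param calibration A `calibration_result` covering every material in the
#'   catalogue.
#' @param required_P Power density the experiment needs, W/cm^2.
#' @param params A [thermal_params()].
#' @param safety_factor Operating margin (default 0.70).
#' @return Data frame sorted by predicted threshold with columns
#'   `grid_id`, `film_material`, `eta_c`, `square_size_um`,
#'   `predicted_pmax`, `bound`, `recommended_P`, `usable`.
#' @export
rank_grids <- function(cat_df, calibration, required_P,
                       params = calibration$params, safety_factor = 0.70) {
  stopifnot(required_P > 0)
  if (nrow(cat_df) == 0) {
    return(data.frame(grid_id = character(0), film_material = character(0),
                      eta_c = numeric(0), square_size_um = numeric(0),
                      predicted_pmax = numeric(0), bound = character(0),
                      recommended_P = numeric(0), usable = logical(0)))
  }
  if (!"eta_c" %in% names(cat_df)) {
    cat_df$eta_c <- vapply(seq_len(nrow(cat_df)), function(i)
      carbon_area_fraction(catalogue_pattern(cat_df[i, ])), numeric(1))
  }
  preds <- lapply(seq_len(nrow(cat_df)), function(i)
    predict_threshold(catalogue_spec(cat_df[i, ]), calibration, params))
  out <- data.frame(
    grid_id = cat_df$grid_id,
    film_material = cat_df$film_material,
    eta_c = cat_df$eta_c,
    square_size_um = cat_df$square_size_um,
    predicted_pmax = vapply(preds, `[[`, numeric(1), "pmax"),
    bound = vapply(preds, `[[`, character(1), "bound"),
    stringsAsFactors = FALSE)
  out$recommended_P <- safety_factor * out$predicted_pmax
  out$usable <- required_P <= out$recommended_P
  ord <- order(-out$predicted_pmax, out$eta_c, out$square_size_um,
               out$grid_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
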