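.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare candidate structures against a SANS curve
#'
#' End-to-end single-curve workflow: Guinier analysis of the data (and
#' molecular weight when the concentration and contrast composition allow
#' it), pair-distance distributions from the data (IFT) and from each model,
#' predicted Debye curves, and a chi-square ranking of the candidate
#' structures.
#'
#' @param structures named list of `structure_model`s
#' @param curve experimental [scattering_curve()] with uncertainties
#' @param contrast a [contrast_model()], or `NULL` for structures carrying
#'   explicit weights
#' @param concentration_mg_ml optional concentration for the I(0) molecular
#'   weight estimate (needs absolute-scale data and a protein composition)
#' @param dmax assumed maximum dimension for the IFT; `"auto"` estimates it
#'   from the largest model
#' @param bin_width Debye histogram bin width, A
#' @param qrg_limit Guinier window bound
#' @param out_dir if given, JSON report and TSV tables are written there
#' @return List of class `sans_report`: `guinier`, `mw_kda` (or `NA`),
#'   `ift`, `model_pddf` (per structure), `fits` (data.frame ranked by
#'   chi2), `config`.
#' @export
run_structure_vs_sans <- function(structures, curve, contrast = NULL,
                                  concentration_mg_ml = NULL, dmax = "auto",
                                  bin_width = 0.5, qrg_limit = 1.3,
                                  out_dir = NULL) {
  stopifnot(length(structures) >= 1)
  if (is.null(names(structures)))
    names(structures) <- paste0("model", seq_along(structures))
  gui <- guinier_fit(curve, qrg_limit = qrg_limit)
  pddfs <- lapply(structures, model_pddf, contrast = contrast, dr = 1)
  if (identical(dmax, "auto"))
    dmax <- max(vapply(pddfs, `[[`, 0, "dmax")) * 1.05
  ift_res <- ift(curve, dmax = dmax)
  fits <- do.call(rbind, lapply(names(structures), function(nm) {
    mod <- debye_curve(structures[[nm]], contrast, q_grid = curve$q,
                       bin_width = bin_width)
    ft <- fit_scale_background(mod, curve)
    data.frame(model = nm, chi2 = ft$chi2_reduced, scale = ft$scale,
               background = ft$background,
               rg_coord = radius_of_gyration(
                 structures[[nm]],
                 weighting = if (is.null(contrast) &&
                                 !is.null(structures[[nm]]$atoms$b)) "excess_b" else "mass",
                 contrast = contrast),
               rg_guinier = guinier_fit(mod, qrg_limit = qrg_limit)$rg)
  }))
  fits <- fits[order(fits$chi2), ]
  rownames(fits) <- NULL
  mw <- NA_real_
  if (!is.null(concentration_mg_ml) && !is.null(contrast)) {
    cs <- contrast_summary(structures[[1]], contrast)
    mw <- molecular_weight_from_i0(gui$i0, concentration_mg_ml,
                                   cs$drho_m_cm_per_g)
  }
  config <- list(bin_width = bin_width, qrg_limit = qrg_limit, dmax = dmax,
                 concentration_mg_ml = concentration_mg_ml,
                 contrast = if (is.null(contrast)) "explicit atom weights"
                 else unclass(contrast)[c("d2o_fraction", "exchanged_fraction")])
  rep <- structure(list(guinier = gui, mw_kda = mw, ift = ift_res,
                        model_pddf = pddfs, fits = fits, config = config),
                   class = "sans_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(fits, file.path(out_dir, "model_fits.tsv"))
    jsonlite::write_json(
      list(guinier = list(rg = gui$rg, rg_se = gui$rg_se, i0 = gui$i0),
           mw_kda = mw, ift_alpha = ift_res$alpha,
           ift_chi2 = ift_res$fit$chi2_reduced,
           fits = fits, config = config),
      file.path(out_dir, "sans_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(pddfs))
      write_pddf(pddfs[[nm]], file.path(out_dir, paste0("pddf_", nm, ".out")))
    write_pddf(ift_res$pd, file.path(out_dir, "pddf_data.out"))
  }
  rep
}

#' @export
print.sans_report <- function(x, ...) {
  cat("SANS report\n")
  print(x$guinier)
  if (is.finite(x$mw_kda)) cat(sprintf("MW from I(0): %.0f kDa\n", x$mw_kda))
  cat("model ranking:\n")
  print(x$fits[, c("model", "chi2", "rg_coord", "rg_guinier")], digits = 4)
  invisible(x)
}

#' Rank an ensemble against a SANS curve and map it onto a landscape
#'
#' Fits every sampled trajectory frame to the data ([rank_frames_by_sans()]),
#' exports the best frame, and (optionally) builds or reuses a PCA landscape
#' with per-frame chi-square annotation.
#'
#' @param traj a `trajectory`
#' @param curve experimental [scattering_curve()] with uncertainties
#' @param contrast a [contrast_model()] or `NULL`
#' @param stride frame stride for the ranking
#' @param landscape an existing [pca_landscape()], `TRUE` to build one from
#'   `traj`, or `NULL` to skip
#' @param landscape_selection selection for a newly built landscape
#' @param bin_width Debye histogram bin width
#' @param out_dir if given, ranking TSV, best-frame PDB and projection TSV
#'   are written there
#' @return List of class `ensemble_report`: `ranking`, `best_frame`
#'   (index), `best_structure`, `projections` (with chi2 annotation, or
#'   `NULL`), `landscape`.
#' @export
run_ensemble_fit <- function(traj, curve, contrast = NULL, stride = 1,
                             landscape = NULL, landscape_selection = "all",
                             bin_width = 0.5, out_dir = NULL) {
  ranking <- rank_frames_by_sans(traj, curve, contrast, stride = stride,
                                 bin_width = bin_width)
  best <- ranking$frame[1]
  best_structure <- frame_structure(traj, best)
  proj <- NULL
  if (isTRUE(landscape))
    landscape <- pca_landscape(traj, selection = landscape_selection)
  if (inherits(landscape, "landscape")) {
    sampled <- lapply(ranking$frame[order(ranking$frame)],
                      function(f) frame_structure(traj, f))
    chi2_in_frame_order <- ranking$chi2[order(ranking$frame)]
    proj <- project_onto_landscape(landscape, sampled,
                                   annotation = chi2_in_frame_order)
    proj$frame <- sort(ranking$frame)
  }
  rep <- structure(list(ranking = ranking, best_frame = best,
                        best_structure = best_structure,
                        projections = proj, landscape = landscape),
                   class = "ensemble_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(ranking, file.path(out_dir, "frame_ranking.tsv"))
    write_structure(best_structure, file.path(out_dir, "best_frame.pdb"))
    if (!is.null(proj)) .write_tsv(proj, file.path(out_dir, "landscape_projections.tsv"))
  }
  rep
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("ensemble fit: %d frames ranked; best frame %d (chi2 = %.2f)\n",
              nrow(x$ranking), x$best_frame, x$ranking$chi2[1]))
  invisible(x)
}
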