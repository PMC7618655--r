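# Evaluation-run driver: mirrors the layout of a localization table
# (rP2P/rP2C mean/median/95%ile) and an agreement table (ICC + CI, MAD + SD,
# Bland-Altman bias + SD) comparing automated vs ground-truth aTFA for both
# the FTS and FNTS constructions.

#' Evaluate a set of predictions against ground truth
#'
#' Per image: mean P2P and P2C over points, divided by the plateau-corner
#' reference length and expressed in percent (rP2P, rP2C; rP2C <= rP2P is
#' asserted per image since every ground-truth counterpart lies on its own
#' polyline). Over images: mean/median/95th percentile of the per-image
#' values. Agreement: automated vs ground-truth aTFA series for FTS and
#' FNTS. Samples with missing predictions are listed and skipped; the run
#' continues with the intersection.
#'
#' @param gt_sets named list of ground-truth [landmark_set()]s (names = ids).
#' @param pred_sets named list of predicted landmark sets (subset of ids).
#' @param out_dir optional directory: writes `localization.csv`,
#'   `agreement.csv` and optional Bland-Altman plots.
#' @param ba_plots also write Bland-Altman PDF plots (needs `out_dir`).
#' @return list: `localization` (data.frame), `agreement` (data.frame),
#'   `per_image` (data.frame), `missing` (character ids).
#' @export
evaluate_run <- function(gt_sets, pred_sets, out_dir = NULL,
                         ba_plots = FALSE) {
  ids <- names(gt_sets)
  missing <- setdiff(ids, names(pred_sets))
  if (length(missing)) {
    warning("evaluate_run: missing predictions for: ",
            paste(missing, collapse = ", "))
  }
  use <- intersect(ids, names(pred_sets))
  if (!length(use)) stop("evaluate_run: no overlapping ids")
  per <- lapply(use, function(id) {
    gt <- gt_sets[[id]]; pr <- pred_sets[[id]]
    ref <- reference_length(gt)
    rp2p <- 100 * mean(p2p(pr, gt)) / ref
    rp2c <- 100 * mean(p2c(pr, gt)) / ref
    stopifnot(rp2c <= rp2p + 1e-12)  # metric-ordering invariant
    data.frame(id = id, ref_length = ref, rP2P = rp2p, rP2C = rp2c,
               atfa_fts_gt = atfa(gt, "fts")$angle,
               atfa_fnts_gt = atfa(gt, "fnts")$angle,
               atfa_fts_pred = atfa(pr, "fts")$angle,
               atfa_fnts_pred = atfa(pr, "fnts")$angle,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  loc <- rbind(
    data.frame(metric = "rP2P", t(summarize_localization(per$rP2P))),
    data.frame(metric = "rP2C", t(summarize_localization(per$rP2C))))
  agree_row <- function(method, auto, gtv) {
    icc <- icc_agreement(auto, gtv)
    mad <- mad_agreement(auto, gtv)
    ba <- bland_altman(auto, gtv,
                       plot_file = if (ba_plots && !is.null(out_dir)) {
                         file.path(out_dir, sprintf("ba_%s.pdf", tolower(method)))
                       })
    data.frame(method = method, n = icc$n,
               icc = icc$icc, icc_lo = icc$ci[1], icc_hi = icc$ci[2],
               mad = mad$mad, mad_sd = mad$sd,
               baa_bias = ba$bias, baa_sd = ba$sd,
               loa_lo = ba$loa[1], loa_hi = ba$loa[2],
               flag = if (is.null(icc$flag)) "" else icc$flag,
               stringsAsFactors = FALSE)
  }
  agr <- rbind(agree_row("FTS", per$atfa_fts_pred, per$atfa_fts_gt),
               agree_row("FNTS", per$atfa_fnts_pred, per$atfa_fnts_gt))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(loc, file.path(out_dir, "localization.csv"), row.names = FALSE)
    write.csv(agr, file.path(out_dir, "agreement.csv"), row.names = FALSE)
    write.csv(per, file.path(out_dir, "per_image.csv"), row.names = FALSE)
  }
  list(localization = loc, agreement = agr, per_image = per,
       missing = missing)
}
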