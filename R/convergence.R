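#' Mesh-refinement ladder for a CSI test
#'
#' Re-runs a coin-shaped-implant test at increasing mesh refinement and
#' tabulates the peak metrics, as a discretisation-adequacy check: at an
#' adequate resolution one further refinement changes the peak tangential
#' force by only a few percent.
#'
#' @param cfg A [csi_config()].
#' @param test Test id, see [run_csi_test()].
#' @param refinements Integer refinement factors to run.
#' @return A tibble with one row per refinement level: element count, the
#'   peak metrics, and the relative change of `F_x_max` between consecutive
#'   levels.
#' @export
csi_convergence <- function(cfg = csi_config(), test = "IIa",
                            refinements = c(1L, 2L)) {
  rows <- lapply(refinements, function(r) {
    cfg$refine <- as.integer(r)
    m <- build_csi(cfg)
    h <- run_csi_test(m, test = test, cfg = cfg)
    dplyr::bind_cols(tibble::tibble(refine = r, n_elems = nrow(m$mesh$elems)),
                     peak_metrics(h))
  })
  out <- dplyr::bind_rows(rows)
  out$dF_rel <- c(NA, abs(diff(out$F_x_max)) / abs(out$F_x_max[-nrow(out)]))
  out
}
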