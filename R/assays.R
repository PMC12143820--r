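#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (target_ct - reference_ct)_treated - (target_ct -
#' reference_ct)_control`; the returned relative expression is `2^-ddCt`.
#' Swapping treated and control inverts the result exactly.
#'
#' @param treated,control lists (or one-row data.frames) with `target_ct`
#'   and `reference_ct` cycle-threshold values.
#' @return Relative expression of the target gene in treated vs control,
#'   normalized to the reference gene.
#' @examples
#' ddct_relative_expression(list(target_ct = 25, reference_ct = 20),
#'                          list(target_ct = 24, reference_ct = 20))
#' @export
ddct_relative_expression <- function(treated, control) {
  cts <- c(treated$target_ct, treated$reference_ct,
           control$target_ct, control$reference_ct)
  if (length(cts) != 4 || any(!is.finite(cts)))
    stop("all four Ct values must be finite")
  ddct <- (treated$target_ct - treated$reference_ct) -
    (control$target_ct - control$reference_ct)
  2^(-ddct)
}

#' Dual-luciferase activity normalized to a reference construct
#'
#' The Firefly/Renilla ratio of the test well divided by the Firefly/Renilla
#' ratio of the reference (empty-vector) well.
#'
#' @param firefly,renilla test-well luminescence; `renilla` must be
#'   positive.
#' @param firefly_ref,renilla_ref reference-well luminescence; both must be
#'   positive.
#' @return Normalized enhancer activity.
#' @export
luciferase_normalized_activity <- function(firefly, renilla,
                                           firefly_ref, renilla_ref) {
  if (any(c(renilla, renilla_ref, firefly_ref) <= 0))
    stop("renilla, renilla_ref and firefly_ref must be positive")
  (firefly / renilla) / (firefly_ref / renilla_ref)
}

#' ChIP-qPCR fold enrichment over an IgG control
#'
#' `2^(ct_control_igg - ct_specific)`: each cycle the specific antibody
#' comes in below the IgG control doubles the enrichment.
#'
#' @param ct_specific Ct of the specific-antibody immunoprecipitation.
#' @param ct_control_igg Ct of the IgG control immunoprecipitation.
#' @return Fold enrichment (> 0).
#' @export
chip_qpcr_fold_enrichment <- function(ct_specific, ct_control_igg) {
  if (any(!is.finite(c(ct_specific, ct_control_igg))))
    stop("Ct values must be finite")
  2^(ct_control_igg - ct_specific)
}
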