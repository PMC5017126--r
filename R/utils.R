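# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Fold change from qPCR cycle thresholds (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_treated - dCt_control`; fold change = `2^-ddCt`, assuming
#' equivalent primer amplification efficiencies.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (finite).
#' @return Fold change (> 0).
#' @export
#' @examples
#' delta_delta_ct(20, 15, 22, 15) # 4
delta_delta_ct <- function(ct_target_treated, ct_ref_treated,
                           ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(is.finite(cts))) abort("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Area under a growth curve
#'
#' Trapezoid-rule area of tumour volume over time, in volume x time units
#' (e.g. mm^3 * day).
#'
#' @param times strictly increasing time points (>= 2).
#' @param volumes non-negative volumes, same length as `times`.
#' @return Area under the curve.
#' @export
#' @examples
#' growth_auc(c(0, 5, 10), c(0, 50, 200)) # 750
growth_auc <- function(times, volumes) {
  if (length(times) != length(volumes) || length(times) < 2) {
    abort("`times` and `volumes` must have equal length >= 2")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  if (any(volumes < 0)) abort("`volumes` must be non-negative")
  sum(diff(times) * (head(volumes, -1) + tail(volumes, -1)) / 2)
}
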