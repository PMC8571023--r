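# Blood-brain-barrier partitioning (logBB) from two published linear
# models in AlogP and topological polar surface area, plus the CNS
# permeation flags derived from them. logBB is the log10 brain-to-blood
# concentration ratio; values above 0 indicate favorable CNS penetration.

#' Clark-model logBB
#'
#' logBB = 0.152 AlogP - 0.0148 PSA + 0.139.
#'
#' @param alogp atom-contribution logP.
#' @param psa topological polar surface area in A^2 (>= 0).
#' @return logBB (unitless).
#' @examples
#' logbbClark(0.98, 88.18)
#' @export
logbbClark <- function(alogp, psa) {
  .checkBBBInputs(alogp, psa)
  0.152 * alogp - 0.0148 * psa + 0.139
}

#' Rishton-model logBB
#'
#' logBB = 0.155 AlogP - 0.01 PSA + 0.164.
#'
#' @inheritParams logbbClark
#' @return logBB (unitless).
#' @examples
#' logbbRishton(4.36, 38.77)
#' @export
logbbRishton <- function(alogp, psa) {
  .checkBBBInputs(alogp, psa)
  0.155 * alogp - 0.01 * psa + 0.164
}

.checkBBBInputs <- function(alogp, psa) {
  if (any(!is.finite(alogp)) || any(!is.finite(psa)))
    stop("alogp and psa must be finite", call. = FALSE)
  if (any(psa < 0)) stop("psa must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Score and classify BBB permeation
#'
#' Evaluates both linear logBB models on a descriptor table and flags CNS
#' permeation: \code{optimal} requires a strictly positive logBB under
#' both models (the models disagree in slope, so a compound is only called
#' favorable when they agree), and \code{psa_cns_ok} flags a polar surface
#' area below the CNS window upper bound (70 A^2 by default; the
#' literature window is 60-70 A^2).
#'
#' @param descriptors data.frame with columns \code{id} (or
#'   \code{compound}), \code{alogp} and \code{psa}.
#' @param psaMax CNS upper bound on PSA, in A^2.
#' @return the input with columns
#'   \code{logbb_cl, logbb_ri, optimal, psa_cns_ok} appended.
#' @examples
#' classifyBBB(data.frame(id = "donepezil", alogp = 4.36, psa = 38.77))
#' @export
classifyBBB <- function(descriptors, psaMax = 70) {
  if (!"id" %in% names(descriptors) && "compound" %in% names(descriptors))
    names(descriptors)[names(descriptors) == "compound"] <- "id"
  need <- c("id", "alogp", "psa")
  if (!all(need %in% names(descriptors)))
    stop("descriptor table requires columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  descriptors$logbb_cl <- logbbClark(descriptors$alogp, descriptors$psa)
  descriptors$logbb_ri <- logbbRishton(descriptors$alogp, descriptors$psa)
  descriptors$optimal <- descriptors$logbb_cl > 0 &
    descriptors$logbb_ri > 0
  descriptors$psa_cns_ok <- descriptors$psa < psaMax
  descriptors
}
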