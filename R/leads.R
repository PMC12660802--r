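#' Bipolar limb leads from electrode potentials
#'
#' Computes Einthoven's bipolar leads from the left-arm (LA), right-arm (RA)
#' and left-leg (LL) electrode potentials:
#' lead I = LA - RA, lead II = LL - RA, lead III = LL - LA.
#' The identity II = I + III holds exactly by construction.
#'
#' @param la,ra,ll Numeric vectors of equal length: electrode potentials in
#'   volts.
#' @return A list with numeric elements `I`, `II`, `III`.
#' @export
#' @examples
#' derive_bipolar_leads(1.0, 0.2, 0.5)
derive_bipolar_leads <- function(la, ra, ll) {
  la <- as.numeric(la); ra <- as.numeric(ra); ll <- as.numeric(ll)
  if (length(la) != length(ra) || length(la) != length(ll)) {
    stop("electrode series must have equal lengths")
  }
  if (!all(is.finite(la), is.finite(ra), is.finite(ll))) {
    stop("electrode series must be finite")
  }
  list(I = la - ra, II = ll - ra, III = ll - la)
}

#' Augmented limb leads from the bipolar leads
#'
#' Goldberger's augmented leads are linear combinations of the bipolar
#' leads: aVL = (I - III)/2, aVF = (II + III)/2, aVR = -(I + II)/2.
#' When the inputs satisfy II = I + III (as any physical lead set does),
#' aVR + aVL + aVF = 0.
#'
#' @param lead_i,lead_ii,lead_iii Numeric vectors of equal length.
#' @return A list with numeric elements `aVR`, `aVL`, `aVF`.
#' @export
derive_augmented_leads <- function(lead_i, lead_ii, lead_iii) {
  lead_i <- as.numeric(lead_i)
  lead_ii <- as.numeric(lead_ii)
  lead_iii <- as.numeric(lead_iii)
  n <- length(lead_i)
  if (length(lead_ii) != n || length(lead_iii) != n) {
    stop("lead series must have equal lengths")
  }
  list(aVR = -(lead_i + lead_ii) / 2,
       aVL = (lead_i - lead_iii) / 2,
       aVF = (lead_ii + lead_iii) / 2)
}
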