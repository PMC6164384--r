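# IC50 / pIC50 transforms and activity-class labelling.
#
# Molecules are assayed in uM and converted to pIC50 = -log10(IC50 in
# mol/L) = 6 - log10(IC50 in uM).  Extract-type samples (crude extracts,
# fractions) are assayed in ug/mL, where no molar conversion exists, and
# are labelled by the 156 ug/mL screening cutoff only.

#' Convert IC50 (uM) to pIC50
#'
#' `pIC50 = -log10(IC50 * 1e-6) = 6 - log10(IC50_uM)`.
#'
#' @param ic50_um Positive IC50 values in micromolar.
#' @return pIC50 values.
#' @examples
#' ic50_um_to_pic50(10)    # 5
#' ic50_um_to_pic50(5.75)  # 5.24 (2 dp)
#' @export
ic50_um_to_pic50 <- function(ic50_um) {
  stopifnot(is.numeric(ic50_um))
  if (any(!is.finite(ic50_um)) || any(ic50_um <= 0)) {
    stop("IC50 must be finite and positive", call. = FALSE)
  }
  6 - log10(ic50_um)
}

#' Convert pIC50 back to IC50 (uM)
#'
#' @param pic50 pIC50 values.
#' @return IC50 in micromolar.
#' @export
pic50_to_ic50_um <- function(pic50) {
  stopifnot(is.numeric(pic50))
  10^(6 - pic50)
}

.MOLECULE_BINARY <- c("active", "inactive")
.MOLECULE_TERNARY <- c("active-to-very-active", "active-to-moderate-active",
                       "inactive")
.EXTRACT_CLASSES <- c("moderate-active-to-active", "inactive")

#' Label molecules by IC50 thresholds
#'
#' Two schemes over IC50 in uM:
#' * `"binary"`: active if IC50 <= 10 uM (hit-to-lead cutoff), else
#'   inactive.
#' * `"ternary"` (used for stratified partitioning):
#'   active-to-very-active if IC50 < 10 uM, active-to-moderate-active if
#'   10 <= IC50 < 50 uM, inactive if IC50 >= 50 uM.
#'
#' @param ic50_um Positive IC50 values in micromolar.
#' @param scheme `"binary"` or `"ternary"`.
#' @return Factor of class labels.
#' @examples
#' label_molecule(c(9.9, 10, 50), "ternary")
#' @export
label_molecule <- function(ic50_um, scheme = c("binary", "ternary")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(ic50_um))
  if (any(!is.finite(ic50_um)) || any(ic50_um <= 0)) {
    stop("IC50 must be finite and positive", call. = FALSE)
  }
  if (scheme == "binary") {
    factor(ifelse(ic50_um <= 10, "active", "inactive"),
           levels = .MOLECULE_BINARY)
  } else {
    lab <- ifelse(ic50_um < 10, .MOLECULE_TERNARY[1],
                  ifelse(ic50_um < 50, .MOLECULE_TERNARY[2],
                         .MOLECULE_TERNARY[3]))
    factor(lab, levels = .MOLECULE_TERNARY)
  }
}

#' Label extract-type samples by the 156 ug/mL cutoff
#'
#' Moderate-active-to-active if IC50 < 156 ug/mL (strict), inactive
#' otherwise.  Censored assays (no IC50 computable within the tested
#' concentration range, i.e. IC50 >= top dose) are always inactive.
#'
#' @param ic50_ugml IC50 values in ug/mL (positive; ignored where
#'   `censored`).
#' @param censored Logical vector; `TRUE` marks censored-at-max assays.
#' @param threshold Cutoff in ug/mL; default 156.
#' @return Factor with levels `moderate-active-to-active`, `inactive`.
#' @examples
#' label_extract(c(33.95, 156, 9.8))
#' @export
label_extract <- function(ic50_ugml, censored = FALSE, threshold = 156) {
  censored <- rep_len(as.logical(censored), length(ic50_ugml))
  ok <- censored | (is.finite(ic50_ugml) & ic50_ugml > 0)
  if (any(!ok)) stop("IC50 must be positive (or censored)", call. = FALSE)
  lab <- ifelse(!censored & ic50_ugml < threshold,
                .EXTRACT_CLASSES[1], .EXTRACT_CLASSES[2])
  factor(lab, levels = .EXTRACT_CLASSES)
}
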