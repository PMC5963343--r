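#' Define an assay panel
#'
#' An assay panel groups the target (isoform-specific) assays with the
#' housekeeping reference assays used to normalize them. Targets and
#' references must be disjoint, and at least one reference is required;
#' in practice two references per tissue context are used so that the final
#' expression change can be averaged over both normalizations.
#'
#' @param targets Character vector of target assay names.
#' @param references Character vector of reference (housekeeping) assay names.
#' @param amplicon_size_bp Optional named integer vector of amplicon sizes in
#'   base pairs, for record keeping.
#' @return An object of class `assay_panel`.
#' @examples
#' assay_panel(c("GBAtv1", "GBAtv2"), c("ACTB", "GUSB"))
#' @export
assay_panel <- function(targets, references, amplicon_size_bp = NULL) {
  if (!is.character(targets) || length(targets) < 1L) {
    abort_validation("`targets` must be a non-empty character vector.")
  }
  if (!is.character(references) || length(references) < 1L) {
    abort_validation("`references` must contain at least one reference assay.")
  }
  shared <- intersect(targets, references)
  if (length(shared) > 0L) {
    abort_validation(sprintf(
      "Targets and references must be disjoint; shared: %s",
      paste(shared, collapse = ", ")
    ))
  }
  if (!is.null(amplicon_size_bp)) {
    if (is.null(names(amplicon_size_bp)) || any(amplicon_size_bp <= 0)) {
      abort_validation("`amplicon_size_bp` must be a named vector of positive sizes.")
    }
  }
  structure(
    list(
      targets = targets,
      references = references,
      amplicon_size_bp = amplicon_size_bp
    ),
    class = "assay_panel"
  )
}

#' @export
print.assay_panel <- function(x, ...) {
  cat("<assay_panel>\n")
  cat("  targets:   ", paste(x$targets, collapse = ", "), "\n")
  cat("  references:", paste(x$references, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in panels for brain and blood tissue contexts
#'
#' The GBA isoform panel quantifies transcript variants GBAtv1, GBAtv2 and
#' GBAtv5 with isoform-specific assays. Brain samples are normalized against
#' beta-actin (ACTB) and beta-glucuronidase (GUSB); blood samples against
#' ACTB and porphobilinogen deaminase (PBGD). Amplicon sizes are carried as
#' metadata.
#'
#' @return An [assay_panel()].
#' @examples
#' brain_panel()
#' blood_panel()
#' @export
brain_panel <- function() {
  assay_panel(
    targets = c("GBAtv1", "GBAtv2", "GBAtv5"),
    references = c("ACTB", "GUSB"),
    amplicon_size_bp = c(
      GBAtv1 = 214L, GBAtv2 = 236L, GBAtv5 = 173L,
      ACTB = 228L, GUSB = 176L
    )
  )
}

#' @rdname brain_panel
#' @export
blood_panel <- function() {
  assay_panel(
    targets = c("GBAtv1", "GBAtv2", "GBAtv5"),
    references = c("ACTB", "PBGD"),
    amplicon_size_bp = c(
      GBAtv1 = 214L, GBAtv2 = 236L, GBAtv5 = 173L,
      ACTB = 228L, PBGD = 183L
    )
  )
}

#' Classification thresholds for relative expression calls
#'
#' A fold change is called `decreased` only when the point estimate falls
#' below `decrease` and the upper variance bound does not exceed it;
#' `increased` only when the point estimate exceeds `increase` and the lower
#' bound is at least that large. Everything else is `unchanged`.
#'
#' @param decrease Fold-change threshold below which expression is considered
#'   decreased (default 0.5). Must be in (0, 1).
#' @param increase Fold-change threshold above which expression is considered
#'   increased (default 1.5). Must exceed 1.
#' @param efficiency_tolerance Maximum absolute difference between target and
#'   reference amplification efficiencies for the equal-efficiency ddCt model
#'   to be considered applicable (default 0.1).
#' @return An object of class `classification_thresholds`.
#' @examples
#' classification_thresholds()
#' @export
classification_thresholds <- function(decrease = 0.5, increase = 1.5,
                                      efficiency_tolerance = 0.1) {
  if (!is_scalar_number(decrease) || !is_scalar_number(increase) ||
      !(decrease > 0 && decrease < 1 && increase > 1)) {
    abort_validation("Need 0 < decrease < 1 < increase.")
  }
  if (!is_scalar_number(efficiency_tolerance) || efficiency_tolerance < 0) {
    abort_validation("`efficiency_tolerance` must be a non-negative number.")
  }
  structure(
    list(
      decrease = decrease,
      increase = increase,
      efficiency_tolerance = efficiency_tolerance
    ),
    class = "classification_thresholds"
  )
}

#' @export
print.classification_thresholds <- function(x, ...) {
  cat(sprintf(
    "<classification_thresholds> decrease < %g, increase > %g, |dE| <= %g\n",
    x$decrease, x$increase, x$efficiency_tolerance
  ))
  invisible(x)
}
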