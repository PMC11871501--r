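#' Ordered set of respiratory phases
#'
#' A 4D-CT acquisition is sorted into discrete respiratory phases, by
#' convention labelled as percentages of the breathing cycle.  One phase is
#' designated the reference phase: the planning frame against which all other
#' phases are aligned.  The defaults are ten phases (0%, 10%, ..., 90%) with
#' the 30% phase as reference.
#'
#' @param labels Character vector of distinct phase labels, in cycle order.
#' @param reference Label of the reference phase.  Must be one of `labels`.
#' @return An object of class `phase_set`: a list with elements `labels` and
#'   `reference_index`.
#' @examples
#' ph <- phase_set()
#' n_phases(ph)
#' reference_label(ph)
#' @export
phase_set <- function(labels = paste0(seq(0L, 90L, 10L), "%"),
                      reference = "30%") {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a phase set needs at least 2 phases, got ", length(labels))
  if (anyDuplicated(labels))
    stop("phase labels must be distinct")
  ref_idx <- match(reference, labels)
  if (is.na(ref_idx))
    stop("reference phase '", reference, "' is not among the phase labels")
  structure(list(labels = labels, reference_index = ref_idx),
            class = "phase_set")
}

#' @rdname phase_set
#' @param phases A `phase_set`.
#' @export
n_phases <- function(phases) length(phases$labels)

#' @rdname phase_set
#' @export
reference_label <- function(phases) phases$labels[phases$reference_index]

#' @export
print.phase_set <- function(x, ...) {
  lab <- x$labels
  lab[x$reference_index] <- paste0("[", lab[x$reference_index], "]")
  cat("<phase_set> ", paste(lab, collapse = " "),
      "  (reference in brackets)\n", sep = "")
  invisible(x)
}
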