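#' Quantification parameters
#'
#' Parameters of the read-classification geometry. A mature miR at
#' `[s, e]` tolerates `mir_slack` nt of slop on both sides; the moR window on
#' the offset side of a mature arm spans `mor_extent` nt outward from the
#' arm-proximal base plus `mir_slack` nt into the miR. Reads are assigned to
#' any pri-miR locus within `locus_distance` nt (gap distance), and inserts
#' shorter than `min_insert` nt are discarded before mapping.
#'
#' The constraint `2 * mir_slack + 1 < min_insert` guarantees that no read
#' long enough to survive the insert filter can lie entirely within both the
#' miR window and the same-arm moR window (they overlap by exactly
#' `2 * mir_slack + 1` nt).
#'
#' @param mir_slack Slop in nt on either side of a mature miR (default 3).
#' @param mor_extent Extent in nt of the moR window beyond the mature arm
#'   (default 35).
#' @param locus_distance Maximum gap in nt between a read and a pri-miR
#'   interval for locus assignment (default 50).
#' @param min_insert Minimum insert length in nt kept after trimming
#'   (default 14, i.e. inserts longer than 13 bases).
#' @return An object of class `quant_params`.
#' @examples
#' quant_params()
#' quant_params(mir_slack = 2)
#' @export
quant_params <- function(mir_slack = 3, mor_extent = 35,
                         locus_distance = 50, min_insert = 14) {
  p <- list(mir_slack = as.integer(mir_slack),
            mor_extent = as.integer(mor_extent),
            locus_distance = as.integer(locus_distance),
            min_insert = as.integer(min_insert))
  vals <- unlist(p)
  if (any(is.na(vals)) || any(vals < 0L))
    stop("all quantification parameters must be nonnegative integers")
  if (2L * p$mir_slack + 1L >= p$min_insert)
    stop("2*mir_slack + 1 must be smaller than min_insert ",
         "(miR/moR window exclusivity)")
  structure(p, class = "quant_params")
}

#' @export
print.quant_params <- function(x, ...) {
  cat("quant_params: mir_slack=", x$mir_slack,
      " mor_extent=", x$mor_extent,
      " locus_distance=", x$locus_distance,
      " min_insert=", x$min_insert, "\n", sep = "")
  invisible(x)
}

#' Differential-expression thresholds
#'
#' Thresholds used to classify array genes into down-regulated, up-regulated
#' and unchanged classes. Both inequalities are strict: a gene is regulated
#' when its fold-change magnitude exceeds `fc_cutoff` and its adjusted p
#' value is below `adjp_cutoff`.
#'
#' @param fc_cutoff Fold-change magnitude cutoff, strict (default 1.3).
#' @param adjp_cutoff Adjusted-p cutoff, strict (default 0.002).
#' @return An object of class `de_thresholds`.
#' @examples
#' de_thresholds()
#' @export
de_thresholds <- function(fc_cutoff = 1.3, adjp_cutoff = 0.002) {
  if (!is.numeric(fc_cutoff) || length(fc_cutoff) != 1L || fc_cutoff <= 1)
    stop("fc_cutoff must be a single number > 1")
  if (!is.numeric(adjp_cutoff) || length(adjp_cutoff) != 1L ||
      adjp_cutoff <= 0 || adjp_cutoff >= 1)
    stop("adjp_cutoff must lie in (0, 1)")
  structure(list(fc_cutoff = fc_cutoff, adjp_cutoff = adjp_cutoff),
            class = "de_thresholds")
}

#' @export
print.de_thresholds <- function(x, ...) {
  cat("de_thresholds: |fold change| >", x$fc_cutoff,
      "and adjusted p <", x$adjp_cutoff, "\n")
  invisible(x)
}
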