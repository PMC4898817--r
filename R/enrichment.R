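#' Classify genes into differential-expression classes
#'
#' Applies the fold-change and adjusted-p thresholds (both strict) to a DE
#' table. Fold changes follow the magnitude-sign convention: magnitude >= 1
#' with down-regulation marked by a minus sign. Ratio-style input (values in
#' (0, 1) meaning down) is detected and converted with a warning.
#'
#' @param de A data.frame with columns `gene`, `fold_change`, `adj_p` and
#'   `detected` (logical).
#' @param thresholds A [de_thresholds] object.
#' @return Factor with levels `DOWN`, `UP`, `UNCHANGED`, `NOT_DETECTED`,
#'   one per row of `de`.
#' @examples
#' de <- data.frame(gene = c("a", "b"), fold_change = c(-1.5, 1.2),
#'                  adj_p = c(0.001, 0.5), detected = TRUE)
#' classify_de(de)
#' @export
classify_de <- function(de, thresholds = de_thresholds()) {
  stopifnot(all(c("gene", "fold_change", "adj_p", "detected") %in% names(de)))
  fc <- de$fold_change
  det <- as.logical(de$detected)
  if (any(det & is.na(fc)))
    stop("detected gene with missing fold change")
  if (any(!is.na(fc) & abs(fc) < 1)) {
    warning("fold changes in (0,1) detected: converting ratio-style values ",
            "to signed magnitudes")
    conv <- !is.na(fc) & fc > 0 & fc < 1
    fc[conv] <- -1 / fc[conv]
  }
  p <- de$adj_p
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("adjusted p values must lie in [0, 1]")
  sig <- det & !is.na(fc) & !is.na(p) &
    abs(fc) > thresholds$fc_cutoff & p < thresholds$adjp_cutoff
  cls <- ifelse(!det, "NOT_DETECTED",
         ifelse(sig & fc < 0, "DOWN",
         ifelse(sig & fc > 0, "UP", "UNCHANGED")))
  factor(cls, levels = c("DOWN", "UP", "UNCHANGED", "NOT_DETECTED"))
}

#' Cross-tabulate predicted targets against DE classes
#'
#' Counts how many predicted target genes are down-regulated, up-regulated
#' or unchanged among those detected on the array. Target genes absent from
#' the DE table, or flagged undetected, are excluded from `n_detected`.
#'
#' @param targets A `target_set` from [scan_utrs()], or a character vector
#'   of gene ids.
#' @param de DE table (see [classify_de()]).
#' @param thresholds A [de_thresholds].
#' @return A list of class `cross_tab` with `n_detected`, `k_down`, `k_up`,
#'   `k_unchanged` (always summing to `n_detected`).
#' @export
cross_tab <- function(targets, de, thresholds = de_thresholds()) {
  genes <- if (inherits(targets, "target_set")) target_genes(targets)
           else as.character(targets)
  cls <- classify_de(de, thresholds)
  m <- match(genes, de$gene)
  gcls <- as.character(cls[m])
  gcls[is.na(m)] <- "NOT_DETECTED"
  out <- list(n_detected = sum(gcls != "NOT_DETECTED"),
              k_down = sum(gcls == "DOWN"),
              k_up = sum(gcls == "UP"),
              k_unchanged = sum(gcls == "UNCHANGED"))
  structure(out, class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("cross_tab: ", x$n_detected, " detected targets (",
      x$k_down, " down, ", x$k_up, " up, ", x$k_unchanged,
      " unchanged)\n", sep = "")
  invisible(x)
}

#' Null down-regulation probability from the array
#'
#' The chance-level probability that a detected gene is down-regulated:
#' the fraction of detected genes classed `DOWN` under the thresholds.
#'
#' @param de DE table (see [classify_de()]).
#' @param thresholds A [de_thresholds].
#' @return A probability in `[0, 1]`.
#' @export
estimate_null <- function(de, thresholds = de_thresholds()) {
  cls <- classify_de(de, thresholds)
  det <- cls != "NOT_DETECTED"
  if (!any(det))
    stop("no detected genes in DE table")
  sum(cls == "DOWN") / sum(det)
}

#' Exact upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, computed by log-space summation of
#' the exact terms (log binomial coefficients via `lchoose`, combined with a
#' log-sum-exp) so small tails near machine precision remain accurate.
#'
#' @param n Number of trials.
#' @param k Threshold count (tail includes `k`).
#' @param p0 Success probability.
#' @return The tail probability.
#' @examples
#' binomial_tail(2, 2, 0.5)   # 0.25
#' binomial_tail(50, 24, 0.05)
#' @export
binomial_tail <- function(n, k, p0) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || k > n || p0 < 0 || p0 > 1)
    stop("need 0 <= k <= n and p0 in [0, 1]")
  if (k == 0L) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  j <- k:n
  lt <- lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Seed-window target enrichment against a DE table
#'
#' For each candidate seed window of a small RNA: scan the UTRs for its
#' seed-match pattern, cross-tabulate the hit genes against the DE classes,
#' and compute the exact binomial upper-tail probability of observing at
#' least `k_down` down-regulated genes among `n_detected` detected targets
#' at the null rate `p0`. A Bonferroni column (tail times the number of
#' windows, capped at 1) is reported as supplementary output; the primary
#' ranking uses the raw tails.
#'
#' @param rna Small RNA sequence, or a precomputed [seed_windows()] table.
#' @param utrs Named [Biostrings::DNAStringSet] of 3'UTRs.
#' @param de DE table (see [classify_de()]).
#' @param thresholds A [de_thresholds].
#' @param p0 Null down-probability; `NULL` (default) estimates it from the
#'   array with [estimate_null()].
#' @return A data.frame of class `enrichment_table` with one row per window:
#'   `start`, `pattern`, `n_detected`, `k_down`, `k_up`, `k_unchanged`,
#'   `p0`, `tail_prob`, `bonferroni`, ordered by window start.
#' @export
enrich_windows <- function(rna, utrs, de, thresholds = de_thresholds(),
                           p0 = NULL) {
  win <- if (inherits(rna, "seed_windows")) rna else seed_windows(rna)
  if (is.null(p0)) p0 <- estimate_null(de, thresholds)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    ts <- scan_utrs(win$pattern[i], utrs, window_start = win$start[i])
    ct <- cross_tab(ts, de, thresholds)
    data.frame(start = win$start[i], pattern = win$pattern[i],
               n_detected = ct$n_detected, k_down = ct$k_down,
               k_up = ct$k_up, k_unchanged = ct$k_unchanged, p0 = p0,
               tail_prob = binomial_tail(ct$n_detected, ct$k_down, p0))
  })
  out <- do.call(rbind, rows)
  out$bonferroni <- pmin(out$tail_prob * nrow(out), 1)
  structure(out, class = c("enrichment_table", "data.frame"))
}

#' Rank seed windows by enrichment evidence
#'
#' Sorts ascending by binomial tail probability; ties broken by larger
#' `k_down`, then smaller window start.
#'
#' @param results An `enrichment_table` from [enrich_windows()] (or any
#'   data.frame with `tail_prob`, `k_down`, `start`).
#' @return The table reordered, with a `rank` column prepended.
#' @export
rank_windows <- function(results) {
  ord <- order(results$tail_prob, -results$k_down, results$start)
  out <- results[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Overlap of down-regulated targets across windows
#'
#' Given per-window sets of down-regulated predicted targets, computes each
#' gene's window membership and the tiers of genes predicted by exactly k
#' windows. Genes predicted by at least two windows form the candidate
#' direct-target set.
#'
#' @param down_sets Named list mapping window label to a character vector of
#'   down-regulated target gene ids (>= 2 windows).
#' @return A list of class `overlap_sets` with `membership` (named list:
#'   gene -> window labels), `tiers` (list: tier k -> genes in exactly k
#'   windows) and `at_least_2` (genes in >= 2 windows).
#' @examples
#' overlap_sets(list(w1 = c("g1", "g2"), w2 = "g2", w3 = c("g2", "g3")))
#' @export
overlap_sets <- function(down_sets) {
  if (length(down_sets) < 2L)
    stop("need at least two windows")
  if (is.null(names(down_sets)))
    names(down_sets) <- paste0("w", seq_along(down_sets))
  genes <- sort(unique(unlist(down_sets, use.names = FALSE)))
  membership <- lapply(setNames(genes, genes), function(g)
    names(down_sets)[vapply(down_sets, function(s) g %in% s, logical(1))])
  k <- lengths(membership)
  tiers <- lapply(setNames(seq_along(down_sets),
                           paste0("tier", seq_along(down_sets))),
                  function(i) names(k)[k == i])
  structure(list(membership = membership, tiers = tiers,
                 at_least_2 = names(k)[k >= 2L]),
            class = "overlap_sets")
}

#' @export
print.overlap_sets <- function(x, ...) {
  ks <- lengths(x$tiers)
  cat("overlap_sets:", sum(ks), "genes;",
      paste0(names(ks), "=", ks, collapse = ", "),
      "; >=2 windows:", length(x$at_least_2), "\n")
  invisible(x)
}
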