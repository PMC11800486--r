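#' @name diagnostics
#' @title Diagnostic accuracy and rater agreement
#' @description
#' Contingency construction of binary rim calls against iron-rim ground
#' truth, the derived accuracy metrics with half-up integer-percent
#' rounding, majority-vote consolidation of reader panels, and
#' chance-corrected agreement statistics (Fleiss kappa for a panel, Cohen's
#' kappa for two sessions) with Landis-Koch interpretation bands.
NULL

# round half away from zero at integer precision (so 62.5 -> 63)
round_half_up <- function(x) floor(x + 0.5)

#' Majority vote over a rating matrix
#'
#' @param ratings items x raters matrix of categorical calls (e.g. a
#'   `rating_matrix`). The rater count must be odd so no tie is possible.
#' @return character vector of per-item modal categories.
#' @export
majority_vote <- function(ratings) {
  if (ncol(ratings) %% 2L == 0L)
    stop("majority vote requires an odd number of raters (ties possible otherwise)")
  apply(ratings, 1L, function(r) names(which.max(table(r))))
}

#' Build a 2x2 contingency table of rim calls against iron truth
#'
#' @param calls per-lesion character vector of `"rim+"`/`"rim-"` (names or
#'   `lesion_id` attribute optional; order must match `truth`).
#' @param truth per-lesion character vector of `"iron+"`/`"iron-"`, or a
#'   truth table with an `iron_rim_status` column.
#' @return list of class `contingency_table`: `tp`, `fp`, `fn`, `tn`,
#'   `total`.
#' @export
build_contingency <- function(calls, truth) {
  if (is.data.frame(truth)) truth <- truth$iron_rim_status
  if (length(calls) != length(truth))
    stop("calls and truth cover different lesion sets")
  pos <- calls == "rim+"
  ir <- truth == "iron+"
  out <- list(tp = sum(pos & ir), fp = sum(pos & !ir),
              fn = sum(!pos & ir), tn = sum(!pos & !ir))
  out$total <- out$tp + out$fp + out$fn + out$tn
  structure(out, class = "contingency_table")
}

#' Contingency table from explicit counts
#' @param tp,fp,fn,tn nonnegative integer counts.
#' @return a `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be nonnegative integers")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, total = sum(counts)),
            class = "contingency_table")
}

#' Diagnostic accuracy metrics from a contingency table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV
#' tn/(tn+fn), accuracy (tp+tn)/total. Percentages are rounded half-up to
#' integers (so 10/16 = 62.5\% prints as 63\%); the raw fractions are
#' retained. A zero denominator yields NA with an `undefined` flag rather
#' than an error.
#'
#' @param table a `contingency_table`.
#' @return list of class `diagnostic_metrics` with `percent` (named integer
#'   vector), `fraction` (named numeric vector), `undefined` (named logical
#'   vector), and the source `table`.
#' @export
diagnostic_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  num <- c(sensitivity = table$tp, specificity = table$tn,
           ppv = table$tp, npv = table$tn, accuracy = table$tp + table$tn)
  den <- c(sensitivity = table$tp + table$fn, specificity = table$tn + table$fp,
           ppv = table$tp + table$fp, npv = table$tn + table$fn,
           accuracy = table$total)
  frac <- ifelse(den > 0, num / den, NA_real_)
  structure(list(percent = ifelse(den > 0, round_half_up(100 * num / den), NA_real_),
                 fraction = frac,
                 undefined = den == 0,
                 table = table),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (m in names(x$percent)) {
    if (x$undefined[[m]]) cat(sprintf("%-12s undefined (zero denominator)\n", m))
    else cat(sprintf("%-12s %3d%%  (%.4f)\n", m, x$percent[[m]], x$fraction[[m]]))
  }
  invisible(x)
}

#' Cohen's kappa for two reading sessions
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the product of the two sessions' marginals.
#' When `p_e = 1` (both sessions constant on the same category), kappa is 1
#' if the sessions agree perfectly and NA otherwise.
#'
#' @param session1,session2 equal-length categorical vectors.
#' @return kappa, a single numeric (possibly NA).
#' @export
cohen_kappa <- function(session1, session2) {
  if (length(session1) != length(session2)) stop("sessions differ in length")
  n <- length(session1)
  cats <- union(unique(session1), unique(session2))
  p_o <- mean(session1 == session2)
  p1 <- vapply(cats, function(k) mean(session1 == k), numeric(1))
  p2 <- vapply(cats, function(k) mean(session2 == k), numeric(1))
  p_e <- sum(p1 * p2)
  if (1 - p_e < .Machine$double.eps) {
    if (p_o == 1) return(1)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa for a multi-rater panel
#'
#' Standard formulation: per-item agreement
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))` for `n` raters per item, mean
#' observed agreement `P-bar`, chance agreement `P-bar_e = sum_j p_j^2` from
#' the pooled category proportions, and
#' `kappa = (P-bar - P-bar_e) / (1 - P-bar_e)`.
#'
#' @param ratings items x raters categorical matrix, no missing cells.
#' @return kappa, a single numeric (NA when `P-bar_e = 1` and agreement is
#'   imperfect).
#' @export
fleiss_kappa <- function(ratings) {
  n <- ncol(ratings)
  if (n < 2L) stop("each item needs at least 2 ratings")
  if (any(is.na(ratings))) stop("ratings must have no missing cells")
  cats <- sort(unique(as.vector(ratings)))
  # items x categories count matrix
  nij <- vapply(cats, function(k) rowSums(ratings == k), numeric(nrow(ratings)))
  nij <- matrix(nij, nrow = nrow(ratings))
  p_i <- (rowSums(nij^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(nij) / sum(nij)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    if (p_bar == 1) return(1)
    return(NA_real_)
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Landis-Koch agreement label for a kappa value
#'
#' Default bands: kappa < 0 "poor"; 0-0.20 "slight"; 0.21-0.40 "fair";
#' 0.41-0.60 "moderate"; 0.61-0.80 "substantial"; 0.81-1.00 "almost
#' perfect". Band edges are closed on the right (0.20 is "slight", 0.60 is
#' "moderate").
#'
#' @param kappa numeric, <= 1.
#' @param bands named numeric vector of band upper edges (configurable).
#' @return character label.
#' @export
landis_koch_label <- function(kappa,
                              bands = c(poor = 0, slight = 0.20, fair = 0.40,
                                        moderate = 0.60, substantial = 0.80,
                                        "almost perfect" = 1)) {
  if (any(kappa > 1)) stop("kappa cannot exceed 1")
  vapply(kappa, function(k) {
    if (k < bands[[1]]) return(names(bands)[1])
    names(bands)[min(which(k <= bands[-1])) + 1L]
  }, character(1))
}

#' Agreement statistics for a reader panel with repeat sessions
#'
#' Convenience wrapper computing the Fleiss kappa of a panel's first-session
#' calls and each rater's Cohen kappa across two sessions, with Landis-Koch
#' labels.
#'
#' @param session1,session2 items x raters rating matrices for the two
#'   sessions (same raters, same items).
#' @return list of class `agreement_stats`: `fleiss_kappa`, `fleiss_label`,
#'   `cohen_kappa` (per rater), `cohen_label`.
#' @export
agreement_stats <- function(session1, session2) {
  if (!all(dim(session1) == dim(session2))) stop("sessions differ in shape")
  fk <- fleiss_kappa(session1)
  ck <- vapply(seq_len(ncol(session1)),
               function(r) cohen_kappa(session1[, r], session2[, r]), numeric(1))
  names(ck) <- colnames(session1)
  structure(list(fleiss_kappa = fk, fleiss_label = landis_koch_label(fk),
                 cohen_kappa = ck,
                 cohen_label = vapply(ck, function(k) if (is.na(k)) NA_character_ else landis_koch_label(k), character(1))),
            class = "agreement_stats")
}
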